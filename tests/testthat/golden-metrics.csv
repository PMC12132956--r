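"subject_id","rater_id","laterality","eye_width_mm","mrd1_mm","peak_temporal_offset_mm","peak_height_mm","fissure_obliquity_deg","mpld_0","mpld_15","mpld_30","mpld_45","mpld_60","mpld_75","mpld_90","mpld_105","mpld_120","mpld_135","mpld_150","mpld_165","mpld_180","ratio_105_75","ratio_120_60","ratio_135_45","ratio_150_30","ratio_165_15","ratio_180_0","ratio_total"
"F001","R1","OD",26.61,4.95,1.56,5.06,9.33,9.32,7.29,6.1,5.4,5.02,4.88,4.95,5.24,5.75,6.57,7.8,9.63,12.51,1.07,1.15,1.22,1.28,1.32,1.34,1.23
"F002","R1","OS",22.67,5.68,1.71,5.88,13.06,7.75,6.48,5.77,5.41,5.3,5.41,5.68,6.09,6.59,7.18,7.94,9.02,10.69,1.13,1.24,1.33,1.38,1.39,1.38,1.31
"F003","R1","OD",22.78,3.37,2.15,3.6,12.53,6.49,4.93,4.06,3.57,3.33,3.27,3.37,3.66,4.16,4.96,6.17,7.92,10.56,1.12,1.25,1.39,1.52,1.61,1.63,1.42
"F004","R1","OS",26.46,3.31,1.11,3.36,15.91,7.16,5.45,4.43,3.81,3.46,3.3,3.31,3.48,3.85,4.5,5.61,7.58,11.85,1.05,1.11,1.18,1.27,1.39,1.66,1.28
"M001","R1","OD",22.04,1.69,3.01,1.97,8.43,5.21,3.24,2.38,1.95,1.74,1.66,1.69,1.83,2.14,2.73,3.93,6.31,10.08,1.1,1.23,1.4,1.65,1.95,1.94,1.54
"M002","R1","OS",24.99,3.15,2,3.3,9.39,7.55,5.41,4.24,3.59,3.25,3.11,3.15,3.36,3.81,4.58,5.88,8.02,11.55,1.08,1.17,1.28,1.39,1.48,1.53,1.32
"M003","R1","OS",26.62,1.9,1.34,1.93,3.36,9.19,4.93,3.25,2.49,2.11,1.93,1.9,1.98,2.23,2.72,3.73,6.07,11.89,1.03,1.05,1.09,1.15,1.23,1.29,1.14
"M004","R1","OD",25.96,4.48,2.26,4.67,5.9,9.64,7.11,5.73,4.95,4.55,4.4,4.48,4.8,5.39,6.33,7.73,9.67,12.27,1.09,1.19,1.28,1.35,1.36,1.27,1.26
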