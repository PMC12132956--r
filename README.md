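# bezlid — upper eyelid contour morphometry from Bézier landmarks

Quantitative assessment of the upper eyelid margin matters for diagnosing
ptosis and retraction and for planning and auditing blepharoplasty, but
the usual clinic-room measurements (a ruler held to the face, or digital
calipers on a photograph) capture only one or two distances and repeat
poorly. A practical alternative is to digitize the margin on an external
eye photograph as a **cubic Bézier curve** — two canthal endpoints plus
two interior control points, four clicks in any image program — and
compute every contour metric analytically from those four points.

`bezlid` is the analysis half of that workflow, aimed at oculoplastic and
ophthalmic imaging researchers. From per-eye landmark records (four Bézier
points, two corneal limbus points, the pupil centre, laterality) it
computes:

* **Calibration** — pixels to millimetres from the white-to-white corneal
  diameter (12.0 mm by default, configurable);
* **Normalization** — pupil-centred, y-up, laterality-mirrored anatomical
  frame (nasal = +x, temporal = −x);
* **Metrics** — eye width; MRD1; contour peak height and signed temporal
  offset; palpebral fissure obliquity θ; the 13-angle radial mid-pupil
  lid distance profile MPLD(θ), θ = 0°, 15°, …, 180°, where
  MRD1 ≡ MPLD(90°); and six temporal-to-nasal MPLD ratios
  (105:75 … 180:0) with a summary ratio;
* **Reliability** — two-way random-effects absolute-agreement intraclass
  correlation (single- and average-measure, with McGraw–Wong confidence
  intervals), Bland–Altman limits of agreement, and Welch/Student
  two-group comparisons with cohort summary tables;
* **Simulation** — a synthetic eye generator whose curves are *solved*
  from target metrics (analytic ground truth), used to validate every
  pipeline stage and to model inter-rater noise.

The curve itself is `B(t) = (1−t)³p₀ + 3(1−t)²t·p₁ + 3(1−t)t²·p₂ + t³p₃`.
The contour peak comes from the quadratic roots of `y′(t)`; each MPLD is
the smallest admissible root of the cubic
`sinθ·x(t) − cosθ·y(t) = 0` with non-negative radius — closed-form
geometry, no pixel tracing.

## Worked example

Simulate a study-sized cohort (40 women, 40 men), digitize it with two
simulated raters (0.15 mm click noise), measure, and summarize:

```r
library(bezlid)
cohort  <- generate_cohort(n_female = 40, n_male = 40, seed = 1)
raters  <- simulate_raters(cohort, rater_sd_mm = 0.15)
metrics <- metrics_table(measure_landmarks(raters$rater1))
summarize_cohort(metrics, cohort$sex)
#>                   metric total_mean total_sd F_mean  F_sd M_mean  M_sd  p_value
#>             eye_width_mm      24.92    1.614  24.46 1.537  25.38 1.575 9.66e-03
#>                  mrd1_mm       4.24    0.765   4.60 0.630   3.88 0.724 1.00e-05
#>  peak_temporal_offset_mm       1.42    1.150   1.63 1.020   1.22 1.247 1.10e-01
#>           peak_height_mm       4.38    0.755   4.76 0.591   3.99 0.706 9.81e-07
#>    fissure_obliquity_deg       9.17    3.205  10.17 3.095   8.18 3.033 4.77e-03
```

Read: women's MRD1 averages 4.60 mm against 3.88 mm in men (higher lids),
the contour peak sits ~1.4 mm temporal to the pupil in both sexes (no
significant difference), and the fissure up-slant is ~2° steeper in women
— the familiar sex dimorphism pattern of young adult Asian cohorts, which
the generator's default population emulates.

Inter-rater agreement on contour peak height:

```r
m2 <- metrics_table(measure_landmarks(raters$rater2))
icc_2_1(cbind(metrics$peak_height_mm, m2$peak_height_mm))
#> ICC(A,1) = 0.982 (95% CI 0.972 to 0.989)
#> ICC(A,2) = 0.991 (95% CI 0.986 to 0.994)
#> n = 80 subjects, k = 2 raters
bland_altman(metrics$peak_height_mm, m2$peak_height_mm)
#> Bland-Altman: bias 0.007, SD 0.142, limits [-0.272, 0.285] (n = 80)
```

A single eye, measured end to end:

```r
g <- generate_eye(synthetic_eye_spec())    # defaults: width 25.03, peak 4.29 mm
measure_all(normalize_eye(g$landmarks))
#> Eyelid metrics: subject SYN1, rater R1, OD
#>   eye width       25.03 mm
#>   MRD1             4.18 mm
#>   peak offset      1.58 mm temporal
#>   peak height      4.29 mm
#>   obliquity        8.75 deg
#> MPLD profile (mm by degree):
#>     0    15    30    45    60    75    90   105   120   135   150   165   180
#>  8.60  6.54  5.35  4.66  4.28  4.14  4.18  4.43  4.92  5.71  6.93  8.78 11.69
```

Note MRD1 (4.18) is below the peak height (4.29): the peak sits temporal
to the pupil, so the vertical ray crosses the margin slightly off-peak.

## Command line

A thin wrapper over the same functions (installed at `cli/bezlid` under
the package directory):

```sh
bezlid simulate   --out landmarks.csv --truth truth.csv --seed 7
bezlid measure    --input landmarks.csv --out metrics.csv --corneal-diameter-mm 12
bezlid reliability --rater1 a.csv --rater2 b.csv --metric peak_height_mm
bezlid summarize  --metrics metrics.csv --sex truth.csv
```

Exit codes: 0 success, 1 validation error, 2 I/O error, 64 usage error.

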