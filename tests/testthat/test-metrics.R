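# Contour metrics on the normalized frame.

# symmetric arch of height h over the pupil, half-width hw, canthi at y = 0
symmetric_eye <- function(h = 4, hw = 12.5) {
  # quadratic-like symmetric cubic: peak at t = 0.5 with height h
  cp <- control_polygon(c(hw, 0), c(hw / 3, 4 * h / 3), c(-hw / 3, 4 * h / 3),
                        c(-hw, 0))
  structure(list(curve = cp, scale_mm_per_px = 0.05, laterality = "OD",
                 subject_id = "SYM", rater_id = "R1",
                 corneal_diameter_mm = 12, mirror_policy = "viewer",
                 flip_x = FALSE, reversed = FALSE, pupil_px = c(640, 480),
                 limbus_a_px = c(520, 480), limbus_b_px = c(760, 480)),
            class = "normalized_eye")
}

shift_eye <- function(eye, dx = 0, dy = 0) {
  P <- unclass(eye$curve)
  P[, 1] <- P[, 1] + dx
  P[, 2] <- P[, 2] + dy
  eye$curve <- control_polygon(P[1, ], P[2, ], P[3, ], P[4, ], frame = "mm")
  eye
}

test_that("eye width is the horizontal extent of the endpoints", {
  eye <- symmetric_eye(hw = 12.4)
  expect_equal(eye_width(eye), 24.8)
  # vertical offset between canthi is ignored by definition
  eye2 <- symmetric_eye(hw = 10)
  P <- unclass(eye2$curve); P[4, 2] <- 4
  eye2$curve <- control_polygon(P[1, ], P[2, ], P[3, ], P[4, ], frame = "mm")
  expect_equal(eye_width(eye2), 20)
})

test_that("fissure obliquity measures the canthal line angle", {
  expect_equal(fissure_obliquity(symmetric_eye()), 0)
  eye <- symmetric_eye(hw = 12)
  P <- unclass(eye$curve)
  P[4, 2] <- 24 * tan(pi * 10 / 180)   # lateral canthus raised: +10 degrees
  eye$curve <- control_polygon(P[1, ], P[2, ], P[3, ], P[4, ], frame = "mm")
  expect_equal(fissure_obliquity(eye), 10, tolerance = 1e-12)
  # hand-verified trigonometry on an asymmetric pair
  eye2 <- symmetric_eye()
  P <- unclass(eye2$curve)
  P[1, ] <- c(12.5, -0.8); P[4, ] <- c(-12.3, 2.9)
  eye2$curve <- control_polygon(P[1, ], P[2, ], P[3, ], P[4, ], frame = "mm")
  expect_equal(fissure_obliquity(eye2),
               atan2(2.9 - (-0.8), 12.5 - (-12.3)) * 180 / pi)
})

test_that("the MPLD profile is mirror-symmetric for a symmetric arch", {
  eye <- symmetric_eye(h = 4.2)
  prof <- mpld_profile(eye)
  v <- unclass(prof)
  expect_length(v, 13)
  expect_equal(unname(v[1:6]), unname(rev(v[8:13])), tolerance = 1e-9)
  expect_equal(unname(v[7]), 4.2, tolerance = 1e-12)
  # mrd1 equals the 90-degree entry
  expect_equal(mrd1(eye), unname(v[7]))
})

test_that("profile distances match the dense-sampling oracle on random eyes", {
  set.seed(91)
  for (i in 1:20) {
    cp <- random_lid_curve()
    eye <- symmetric_eye(); eye$curve <- cp
    prof <- unclass(mpld_profile(eye))
    for (j in seq_along(mpld_angles())) {
      orc <- scan_ray_oracle(cp, mpld_angles()[j])
      expect_identical(unname(is.na(prof[j])), is.na(orc$r))
      if (!is.na(prof[j])) expect_lt(abs(unname(prof[j]) - orc$r), 1e-4)
    }
  }
})

test_that("contour peak reports temporal-positive offset and is translation-equivariant", {
  eye <- symmetric_eye(h = 4.0)
  pk <- contour_peak(eye)
  expect_equal(pk$peak_temporal_offset_mm, 0, tolerance = 1e-12)
  expect_equal(pk$peak_height_mm, 4.0, tolerance = 1e-12)
  # shifting the curve 1.5 mm nasally makes the offset -1.5 (nasal peak)
  pk2 <- contour_peak(shift_eye(eye, dx = 1.5))
  expect_equal(pk2$peak_temporal_offset_mm, -1.5, tolerance = 1e-12)
  expect_equal(pk2$peak_height_mm, 4.0, tolerance = 1e-12)
  # when the pupil sits under the peak, mrd1 equals the peak height
  expect_equal(mrd1(eye), contour_peak(eye)$peak_height_mm, tolerance = 1e-12)
})

test_that("temporal-to-nasal ratios divide mirror pairs and summarize", {
  eye <- symmetric_eye()
  ratios <- tn_ratios(mpld_profile(eye))
  expect_equal(unname(ratios[1:6]), rep(1, 6), tolerance = 1e-9)
  expect_equal(unname(ratios[["ratio_total"]]), 1, tolerance = 1e-9)

  # direct division, including a published-means check: a profile with
  # MPLD(180) = 12.15 and MPLD(0) = 9.12 gives 180:0 ratio 1.332
  prof <- mpld_profile(eye)
  v <- unclass(prof)
  v[13] <- 12.15; v[1] <- 9.12
  prof2 <- structure(v, angles = attr(prof, "angles"), class = "mpld_profile")
  r <- tn_ratios(prof2)
  expect_equal(unname(r[["ratio_180_0"]]), 12.15 / 9.12, tolerance = 1e-12)
  expect_equal(round(unname(r[["ratio_180_0"]]), 3), 1.332)

  # zero or missing nasal entries propagate NA per ratio
  v[1] <- 0
  r0 <- tn_ratios(structure(v, angles = attr(prof, "angles"),
                            class = "mpld_profile"))
  expect_true(is.na(r0[["ratio_180_0"]]))
  expect_false(anyNA(r0[1:5]))

  # alternative total definition: ratio of sums
  rs <- tn_ratios(prof2, total = "sum")
  tv <- unclass(prof2)[c(8:13)]; nv <- unclass(prof2)[6:1]
  expect_equal(unname(rs[["ratio_total"]]), sum(tv) / sum(nv))
})

test_that("measure_all assembles consistent metrics and enforces invariants", {
  eye <- symmetric_eye(h = 4.0, hw = 12.5)
  m <- measure_all(eye)
  expect_s3_class(m, "eyelid_metrics")
  expect_equal(m$eye_width_mm, 25.0)
  expect_equal(m$mrd1_mm, 4.0, tolerance = 1e-12)
  expect_equal(m$peak_temporal_offset_mm, 0, tolerance = 1e-12)
  expect_equal(m$fissure_obliquity_deg, 0)
  expect_equal(unname(m$tn_ratios[1:6]), rep(1, 6), tolerance = 1e-9)
  # MRD1 is the profile's 90-degree entry, bit for bit
  expect_identical(m$mrd1_mm, unname(unclass(m$mpld)[7]))

  # wide one-row form
  df <- as.data.frame(m)
  expect_equal(nrow(df), 1L)
  expect_true(all(c("mpld_0", "mpld_90", "mpld_180", "ratio_180_0",
                    "ratio_total") %in% names(df)))
  expect_identical(df$mrd1_mm, df$mpld_90)
})

test_that("peak height dominates MRD1 over a random sweep", {
  set.seed(101)
  for (i in 1:200) {
    cp <- random_lid_curve()
    eye <- symmetric_eye(); eye$curve <- cp
    h <- contour_peak(eye)$peak_height_mm
    m90 <- mrd1(eye)
    if (!is.na(m90)) expect_gte(h, m90 - 1e-12)
  }
})

test_that("metrics are invariant to pixel translation and rescaling", {
  spec <- synthetic_eye_spec(noise_sd_px = 0)
  g <- generate_eye(spec)
  base <- metrics_table(measure_landmarks(g$landmarks))

  # translate the whole landmark set in pixel space
  lm <- g$landmarks
  shift <- c(37.3, 91.1)
  lm_t <- landmark_set(lm$bezier_px + rep(shift, each = 4),
                       lm$limbus_a_px + shift, lm$limbus_b_px + shift,
                       lm$pupil_px + shift, lm$laterality,
                       lm$subject_id, lm$rater_id)
  trans <- metrics_table(measure_landmarks(lm_t))
  expect_equal(trans[, -(1:3)], base[, -(1:3)], tolerance = 1e-9)

  # uniform rescaling of all pixel coordinates (limbus included)
  k <- 1.7
  lm_s <- landmark_set(lm$bezier_px * k, lm$limbus_a_px * k,
                       lm$limbus_b_px * k, lm$pupil_px * k,
                       lm$laterality, lm$subject_id, lm$rater_id)
  scaled <- metrics_table(measure_landmarks(lm_s))
  expect_equal(scaled[, -(1:3)], base[, -(1:3)], tolerance = 1e-9)

  # mm outputs are homogeneous of degree 1 in the corneal diameter constant
  eleven <- metrics_table(measure_landmarks(lm, corneal_diameter_mm = 11))
  mm_cols <- c("eye_width_mm", "mrd1_mm", "peak_temporal_offset_mm",
               "peak_height_mm", grep("^mpld_", names(base), value = TRUE))
  expect_equal(eleven[, mm_cols], base[, mm_cols] * 11 / 12, tolerance = 1e-9)
  expect_equal(eleven$fissure_obliquity_deg, base$fissure_obliquity_deg)
  expect_equal(eleven$ratio_total, base$ratio_total, tolerance = 1e-9)
})
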