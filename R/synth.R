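## Synthetic eye generator. The interior control points are solved, not
## sampled, so that the generated curve's analytic contour peak, endpoints
## and obliquity hit the requested values exactly: the peak is pinned at
## curve parameter t = 1/2, which turns the peak conditions (x, y, y' = 0)
## into linear equations for the interior points. Randomness (cohort draws,
## landmark jitter, rater noise) flows through R's global RNG; seed with
## set.seed() or the `seed` arguments for reproducibility.

#' Specification of one synthetic eye
#'
#' Ground-truth parameters from which [generate_eye()] constructs an eye.
#' Geometry lives in the normalized anatomical frame (mm, pupil origin,
#' nasal = +x); the conversion to pixel landmarks uses `scale_mm_per_px`,
#' `pupil_px` and `laterality` (viewer-oriented mirroring).
#'
#' @param width_mm Horizontal eye width (distance between endpoint
#'   x-coordinates), mm.
#' @param peak_height_mm Contour peak height above the pupil centre, mm.
#' @param peak_temporal_offset_mm Signed temporal offset of the peak from
#'   the pupil centre, mm (positive = temporal).
#' @param obliquity_deg Palpebral fissure obliquity, degrees (positive =
#'   lateral canthus superior).
#' @param pupil_offset_mm Length-2 vector positioning the pupil relative to
#'   the canthi, mm: the first element is how far the pupil sits nasal of
#'   the intercanthal x-midpoint, the second how far above the lateral
#'   canthal endpoint. Anchoring the vertical offset at the lateral canthus
#'   keeps both canthi below the pupil horizontal for any up-slanted
#'   fissure (the medial canthus drops by the obliquity rise), so the
#'   horizontal 0/180-degree MPLD radii are always defined. The default
#'   puts those radii near the anatomically reported ~9 mm (nasal) and
#'   ~12 mm (temporal).
#' @param scale_mm_per_px Calibration scale of the simulated photograph.
#' @param pupil_px Pixel position of the pupil centre in the simulated
#'   image.
#' @param laterality `"OD"` or `"OS"`.
#' @param noise_sd_px Gaussian jitter SD (pixels) applied to the four
#'   digitized Bezier points; 0 = noise-free.
#' @param subject_id,rater_id Identifiers.
#' @return A list of class `synthetic_eye_spec`.
#' @export
synthetic_eye_spec <- function(width_mm = 25.03,
                               peak_height_mm = 4.29,
                               peak_temporal_offset_mm = 1.58,
                               obliquity_deg = 8.75,
                               pupil_offset_mm = c(-0.35, 0.4),
                               scale_mm_per_px = 0.05,
                               pupil_px = c(640, 480),
                               laterality = "OD",
                               noise_sd_px = 0,
                               subject_id = "SYN1",
                               rater_id = "R1") {
  if (width_mm <= 0) stop_validation("width_mm must be positive")
  if (peak_height_mm <= 0) stop_validation("peak_height_mm must be positive")
  if (scale_mm_per_px <= 0) stop_validation("scale_mm_per_px must be positive")
  if (noise_sd_px < 0) stop_validation("noise_sd_px must be non-negative")
  if (!is_point(pupil_offset_mm)) stop_validation("pupil_offset_mm must be an (x, y) pair")
  if (!laterality %in% c("OD", "OS")) stop_validation("laterality must be OD or OS")
  structure(
    list(width_mm = width_mm, peak_height_mm = peak_height_mm,
         peak_temporal_offset_mm = peak_temporal_offset_mm,
         obliquity_deg = obliquity_deg, pupil_offset_mm = pupil_offset_mm,
         scale_mm_per_px = scale_mm_per_px, pupil_px = pupil_px,
         laterality = laterality, noise_sd_px = noise_sd_px,
         subject_id = subject_id, rater_id = rater_id),
    class = "synthetic_eye_spec"
  )
}

## Normalized-frame control polygon whose width, obliquity and analytic
## contour peak match the spec exactly.
solve_spec_curve <- function(spec) {
  w <- spec$width_mm
  mx <- -spec$pupil_offset_mm[1]
  y3 <- -spec$pupil_offset_mm[2]               # lateral canthus depth
  y0 <- y3 - w * tanpi(spec$obliquity_deg / 180)  # medial canthus lower by the rise
  x0 <- mx + w / 2                             # medial / nasal endpoint
  x3 <- mx - w / 2                             # lateral / temporal endpoint
  xs <- -spec$peak_temporal_offset_mm         # requested peak x
  h <- spec$peak_height_mm
  margin <- 0.05 * w
  if (xs >= x0 - margin || xs <= x3 + margin) {
    stop_validation("infeasible spec: peak offset beyond the horizontal extent")
  }
  if (h <= max(y0, y3)) {
    stop_validation("infeasible spec: peak height not above both endpoints")
  }
  ## peak pinned at t = 1/2: B_y(1/2) = h, y'(1/2) = 0, B_x(1/2) = xs
  y1 <- (8 * h - 4 * y0 + 2 * y3) / 6
  y2 <- y0 + y1 - y3
  ssum <- (8 * xs - x0 - x3) / 3              # x1 + x2
  d <- (x0 - x3) / 6                          # spread keeping x(t) monotone
  x1 <- ssum / 2 + d
  x2 <- ssum / 2 - d
  cp <- control_polygon(c(x0, y0), c(x1, y1), c(x2, y2), c(x3, y3), frame = "mm")
  pk <- bezier_peak(cp)
  if (abs(pk$point[["y"]] - h) > 1e-8 || abs(pk$point[["x"]] - xs) > 1e-8) {
    stop_validation("infeasible spec: requested peak is not the global maximum of the solved curve")
  }
  cp
}

#' Generate one synthetic eye with known ground truth
#'
#' Builds the normalized-frame curve from the spec (see
#' [synthetic_eye_spec()]), measures the noise-free ground-truth metrics,
#' and converts the curve into a raw pixel [landmark_set()] (digitization
#' order lateral-first, image y-down, viewer-oriented laterality
#' mirroring), optionally adding Gaussian jitter to the digitized Bezier
#' points. The limbus calibration points are placed one corneal radius
#' either side of the pupil.
#'
#' @param spec A [synthetic_eye_spec()].
#' @param corneal_diameter_mm Corneal diameter used for the simulated
#'   calibration segment, mm.
#' @return A list with `landmarks` (the raw [landmark_set()], jittered if
#'   requested), `truth` (noise-free [measure_all()] result) and `spec`.
#' @export
generate_eye <- function(spec, corneal_diameter_mm = 12) {
  if (!inherits(spec, "synthetic_eye_spec")) {
    stop_validation("spec must be a synthetic_eye_spec")
  }
  cp <- solve_spec_curve(spec)
  eye_true <- structure(
    list(curve = cp, scale_mm_per_px = spec$scale_mm_per_px,
         laterality = spec$laterality, subject_id = spec$subject_id,
         rater_id = spec$rater_id, corneal_diameter_mm = corneal_diameter_mm,
         mirror_policy = "viewer",
         flip_x = spec$laterality == "OS", reversed = TRUE,
         pupil_px = spec$pupil_px,
         limbus_a_px = spec$pupil_px - c((corneal_diameter_mm / 2) / spec$scale_mm_per_px, 0),
         limbus_b_px = spec$pupil_px + c((corneal_diameter_mm / 2) / spec$scale_mm_per_px, 0)),
    class = "normalized_eye")
  truth <- measure_all(eye_true)
  lm <- denormalize_eye(eye_true)
  if (spec$noise_sd_px > 0) {
    jit <- matrix(stats::rnorm(8, 0, spec$noise_sd_px), 4, 2)
    lm <- landmark_set(lm$bezier_px + jit, lm$limbus_a_px, lm$limbus_b_px,
                       lm$pupil_px, lm$laterality, lm$subject_id, lm$rater_id)
  }
  list(landmarks = lm, truth = truth, spec = spec)
}

## normal draw truncated to [lo, hi] (and +/- 4 SD) by rejection
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  lo <- max(lo, mean - 4 * sd)
  hi <- min(hi, mean + 4 * sd)
  if (lo >= hi) stop_validation("invalid population moments: empty truncation range")
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Default population moments for cohort simulation
#'
#' Sex-specific means and SDs of the generator parameters, emulating the
#' summary statistics of a young adult Asian cohort: eye width about 25 mm,
#' contour peak height 3.8-4.7 mm sitting 1.5-1.7 mm temporal to the
#' pupil, and an up-slanted fissure of 7.5-10 degrees. Override any entry
#' to simulate other populations.
#'
#' @return A nested list `list(F = ..., M = ...)`; each sex holds
#'   `mean`/`sd` pairs for `width_mm`, `peak_height_mm`,
#'   `peak_temporal_offset_mm` and `obliquity_deg`.
#' @export
cohort_population <- function() {
  list(
    F = list(width_mm = c(mean = 24.82, sd = 1.82),
             peak_height_mm = c(mean = 4.74, sd = 0.68),
             peak_temporal_offset_mm = c(mean = 1.67, sd = 1.02),
             obliquity_deg = c(mean = 9.98, sd = 3.07)),
    M = list(width_mm = c(mean = 25.25, sd = 2.00),
             peak_height_mm = c(mean = 3.84, sd = 0.93),
             peak_temporal_offset_mm = c(mean = 1.49, sd = 1.33),
             obliquity_deg = c(mean = 7.52, sd = 2.89))
  )
}

#' Generate a synthetic cohort of eyes
#'
#' Draws per-subject ground-truth parameters from truncated normal
#' population distributions (truncation at +/- 4 SD and at physical
#' bounds) and generates one eye per subject via [generate_eye()].
#'
#' @param n_female,n_male Number of subjects per sex (>= 0, at least one
#'   in total).
#' @param population Population moments, shaped like [cohort_population()].
#' @param noise_sd_px Digitization jitter passed to each eye's spec.
#' @param scale_mm_per_px,pupil_px Imaging parameters shared by the cohort.
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   repeated runs are identical.
#' @return A list of class `synthetic_cohort`: `landmarks` (list of
#'   [landmark_set()]), `truth` (data frame of ground-truth metrics, one
#'   row per eye), `sex` (per-eye labels `"F"`/`"M"`), `population`,
#'   `seed`.
#' @export
generate_cohort <- function(n_female = 40, n_male = 40,
                            population = cohort_population(),
                            noise_sd_px = 0,
                            scale_mm_per_px = 0.05,
                            pupil_px = c(640, 480),
                            seed = NULL) {
  if (n_female < 0 || n_male < 0 || n_female + n_male < 1) {
    stop_validation("need at least one subject")
  }
  if (!all(c("F", "M") %in% names(population))) {
    stop_validation("population must have F and M components")
  }
  if (!is.null(seed)) set.seed(seed)
  sexes <- c(rep("F", n_female), rep("M", n_male))
  ids <- c(sprintf("F%03d", seq_len(n_female)), sprintf("M%03d", seq_len(n_male)))
  landmarks <- vector("list", length(sexes))
  truths <- vector("list", length(sexes))
  for (i in seq_along(sexes)) {
    pop <- population[[sexes[i]]]
    for (nm in c("width_mm", "peak_height_mm", "peak_temporal_offset_mm",
                 "obliquity_deg")) {
      mom <- pop[[nm]]
      if (is.null(mom) || anyNA(mom) || mom["sd"] < 0) {
        stop_validation(sprintf("invalid population moments for %s", nm))
      }
    }
    w <- rtrunc_norm(1, pop$width_mm["mean"], pop$width_mm["sd"], lo = 15, hi = 35)
    h <- rtrunc_norm(1, pop$peak_height_mm["mean"], pop$peak_height_mm["sd"],
                     lo = 1, hi = 8)
    off <- rtrunc_norm(1, pop$peak_temporal_offset_mm["mean"],
                       pop$peak_temporal_offset_mm["sd"],
                       lo = -w / 4, hi = w / 4)
    obl <- rtrunc_norm(1, pop$obliquity_deg["mean"], pop$obliquity_deg["sd"],
                       lo = -15, hi = 25)
    lat <- sample(c("OD", "OS"), 1L)
    spec <- synthetic_eye_spec(
      width_mm = w, peak_height_mm = h, peak_temporal_offset_mm = off,
      obliquity_deg = obl, scale_mm_per_px = scale_mm_per_px,
      pupil_px = pupil_px, laterality = lat, noise_sd_px = noise_sd_px,
      subject_id = ids[i])
    g <- generate_eye(spec)
    landmarks[[i]] <- g$landmarks
    truths[[i]] <- g$truth
  }
  structure(
    list(landmarks = landmarks, truth = metrics_table(truths),
         sex = sexes, population = population, seed = seed),
    class = "synthetic_cohort"
  )
}

#' Simulate two raters digitizing the same eyes
#'
#' Models inter-rater variability: each rater's four Bezier points are the
#' true points plus independent Gaussian placement error of SD
#' `rater_sd_mm` (converted to pixels through each eye's own calibration),
#' and rater 2 optionally carries a systematic vertical bias of
#' `rater_bias_mm` (positive = rater 2 places the curve higher).
#'
#' @param landmarks A list of [landmark_set()] (e.g. a
#'   `synthetic_cohort$landmarks`) holding the true digitizations.
#' @param rater_sd_mm Per-point placement noise SD, mm (default 0.15 mm,
#'   about 3 px at a 0.05 mm/px scale -- realistic click precision).
#' @param rater_bias_mm Systematic vertical offset of rater 2, mm.
#' @param corneal_diameter_mm Calibration constant used to convert mm noise
#'   to pixels.
#' @return A list with `rater1` and `rater2`, each a list of
#'   [landmark_set()] with `rater_id` `"R1"` / `"R2"`.
#' @export
simulate_raters <- function(landmarks, rater_sd_mm = 0.15, rater_bias_mm = 0,
                            corneal_diameter_mm = 12) {
  if (inherits(landmarks, "synthetic_cohort")) landmarks <- landmarks$landmarks
  if (inherits(landmarks, "landmark_set")) landmarks <- list(landmarks)
  if (!length(landmarks) ||
      !all(vapply(landmarks, inherits, logical(1), "landmark_set"))) {
    stop_validation("landmarks must be a list of landmark_set objects")
  }
  if (rater_sd_mm < 0) stop_validation("rater_sd_mm must be non-negative")
  perturb <- function(lm, rater_id, bias_mm) {
    scale <- compute_scale(lm$limbus_a_px, lm$limbus_b_px, corneal_diameter_mm)
    sd_px <- rater_sd_mm / scale
    jit <- if (sd_px > 0) matrix(stats::rnorm(8, 0, sd_px), 4, 2) else matrix(0, 4, 2)
    bez <- lm$bezier_px + jit
    bez[, 2] <- bez[, 2] - bias_mm / scale   # image y-down: up = smaller y
    landmark_set(bez, lm$limbus_a_px, lm$limbus_b_px, lm$pupil_px,
                 lm$laterality, lm$subject_id, rater_id)
  }
  list(rater1 = lapply(landmarks, perturb, rater_id = "R1", bias_mm = 0),
       rater2 = lapply(landmarks, perturb, rater_id = "R2", bias_mm = rater_bias_mm))
}
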