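## Eyelid contour metrics, all defined on the normalized (pupil-origin,
## mm, nasal = +x) frame. Angles follow the radial MPLD convention:
## 0 = nasal horizontal, 90 = superior vertical, 180 = temporal horizontal.

#' Canonical MPLD angle grid
#'
#' The 13 radial angles, 0 to 180 degrees in 15-degree steps, at which the
#' mid-pupil lid distance profile is evaluated.
#' @return Numeric vector of 13 angles in degrees.
#' @export
mpld_angles <- function() seq(0, 180, by = 15)

tn_pairs <- function() {
  cbind(temporal = c(105, 120, 135, 150, 165, 180),
        nasal    = c(75,  60,  45,  30,  15,  0))
}

#' Horizontal eye width
#'
#' Distance between the x-coordinates of the two curve endpoints (medial
#' and lateral canthal ends). By definition this is the horizontal extent,
#' not the chord length: a vertical offset between the canthi does not
#' enter.
#'
#' @param eye A [normalize_eye()] result.
#' @return Width in mm.
#' @export
eye_width <- function(eye) {
  stopifnot(inherits(eye, "normalized_eye"))
  P <- unclass(eye$curve)
  abs(P[1, 1] - P[4, 1])
}

#' Palpebral fissure obliquity
#'
#' Angle between the line joining the medial and lateral canthal endpoints
#' and the horizontal, in degrees. Positive when the lateral (temporal)
#' endpoint sits superior to the medial one -- the up-slanted fissure
#' typical of Asian eyelids.
#'
#' @param eye A [normalize_eye()] result.
#' @return Obliquity in degrees.
#' @export
fissure_obliquity <- function(eye) {
  stopifnot(inherits(eye, "normalized_eye"))
  P <- unclass(eye$curve)
  dx <- abs(P[1, 1] - P[4, 1])
  if (dx == 0) stop_validation("degenerate geometry: endpoints share an x-coordinate")
  atan2(P[4, 2] - P[1, 2], dx) * 180 / pi
}

#' Radial mid-pupil lid distance profile
#'
#' Distance from the pupil centre to the upper lid margin along rays at
#' each requested angle (see [ray_intersection()]). Angles whose ray does
#' not meet the curve yield `NA`; horizontal rays legitimately miss a lid
#' arch that stays strictly above the pupil line.
#'
#' @param eye A [normalize_eye()] result.
#' @param angles Angle grid in degrees; defaults to the canonical 13-angle
#'   grid of [mpld_angles()].
#' @return An object of class `mpld_profile`: a named numeric vector of
#'   distances in mm (names are the angles), possibly containing `NA`.
#' @export
mpld_profile <- function(eye, angles = mpld_angles()) {
  stopifnot(inherits(eye, "normalized_eye"))
  if (!is.numeric(angles) || !length(angles) || anyNA(angles) ||
      any(angles < 0 | angles > 180)) {
    stop_validation("angles must be in [0, 180] degrees")
  }
  r <- vapply(angles, function(a) ray_intersection(eye$curve, a)$r, numeric(1))
  structure(r, names = format(angles, trim = TRUE), angles = angles,
            class = "mpld_profile")
}

#' @export
print.mpld_profile <- function(x, ...) {
  cat("MPLD profile (mm by degree):\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Margin reflex distance 1
#'
#' MRD1 is the vertical distance from the pupil centre to the upper lid
#' margin, i.e. the MPLD at 90 degrees.
#'
#' @param eye A [normalize_eye()] result.
#' @return MRD1 in mm (`NA` for the pathological case of a curve that
#'   never crosses the vertical through the pupil).
#' @export
mrd1 <- function(eye) {
  stopifnot(inherits(eye, "normalized_eye"))
  ray_intersection(eye$curve, 90)$r
}

#' Contour peak location and height
#'
#' The contour peak is the point where the y-value of the Bezier curve is
#' largest. Its height is reported above the pupil centre and its
#' horizontal position as a signed temporal offset (positive when the peak
#' lies temporal to the pupil, negative when nasal).
#'
#' @param eye A [normalize_eye()] result.
#' @return A list with `peak_temporal_offset_mm` and `peak_height_mm`.
#' @export
contour_peak <- function(eye) {
  stopifnot(inherits(eye, "normalized_eye"))
  pk <- bezier_peak(eye$curve)
  list(peak_temporal_offset_mm = -pk$point[["x"]],
       peak_height_mm = pk$point[["y"]])
}

#' Temporal-to-nasal MPLD ratios
#'
#' Ratios of the MPLD at each temporal angle to the MPLD at its nasal
#' mirror angle (same inclination from the vertical): 105:75, 120:60,
#' 135:45, 150:30, 165:15 and 180:0. A summary `ratio_total` is appended;
#' its definition is configurable because no single convention is
#' authoritative: `"mean"` (default) is the arithmetic mean of the six pair
#' ratios, `"sum"` is the ratio of the summed temporal to the summed nasal
#' distances.
#'
#' @param profile An [mpld_profile()].
#' @param total Definition of `ratio_total`: `"mean"` or `"sum"`.
#' @return Named numeric vector `ratio_105_75`, ..., `ratio_180_0`,
#'   `ratio_total`, with attribute `total_definition`. Pairs with a missing
#'   or zero nasal entry are `NA`.
#' @export
tn_ratios <- function(profile, total = c("mean", "sum")) {
  if (!inherits(profile, "mpld_profile")) {
    stop_validation("profile must be an mpld_profile")
  }
  total <- match.arg(total)
  angles <- attr(profile, "angles")
  pairs <- tn_pairs()
  val <- unclass(profile)
  get_at <- function(a) {
    i <- match(a, angles)
    if (is.na(i)) NA_real_ else val[i]
  }
  tv <- vapply(pairs[, "temporal"], get_at, numeric(1))
  nv <- vapply(pairs[, "nasal"], get_at, numeric(1))
  ratio <- ifelse(is.na(nv) | is.na(tv) | nv == 0, NA_real_, tv / nv)
  names(ratio) <- sprintf("ratio_%d_%d", pairs[, "temporal"], pairs[, "nasal"])
  rt <- switch(total,
               mean = mean(ratio),
               sum = if (anyNA(tv) || anyNA(nv) || sum(nv) == 0) NA_real_
                     else sum(tv) / sum(nv))
  out <- c(ratio, ratio_total = rt)
  attr(out, "total_definition") <- total
  out
}

#' Measure the full eyelid metric set for one eye
#'
#' Runs every contour metric on a normalized eye and assembles the result:
#' eye width, MRD1, contour peak offset and height, fissure obliquity, the
#' MPLD profile and the temporal-to-nasal ratios. MRD1 is taken from the
#' profile's 90-degree entry, so the identity MRD1 == MPLD(90) holds
#' bit-for-bit. The structural invariant peak height >= MRD1 (the peak is
#' the global maximum of y) is enforced.
#'
#' @param eye A [normalize_eye()] result.
#' @param angles MPLD angle grid; must contain 90 for MRD1.
#' @param ratio_total Passed to [tn_ratios()].
#' @return An object of class `eyelid_metrics`; see [as.data.frame.eyelid_metrics()]
#'   for the flat one-row form.
#' @export
measure_all <- function(eye, angles = mpld_angles(),
                        ratio_total = c("mean", "sum")) {
  stopifnot(inherits(eye, "normalized_eye"))
  ratio_total <- match.arg(ratio_total)
  if (!90 %in% angles) {
    stop_validation("the angle grid must contain 90 degrees (MRD1)")
  }
  profile <- mpld_profile(eye, angles)
  m90 <- unname(unclass(profile)[match(90, angles)])
  pk <- contour_peak(eye)
  if (!is.na(m90) && pk$peak_height_mm < m90 - 1e-9) {
    bz_stop("internal consistency error: contour peak below MPLD(90)",
            "bezlid_internal_error")
  }
  structure(
    list(subject_id = eye$subject_id,
         rater_id = eye$rater_id,
         laterality = eye$laterality,
         eye_width_mm = eye_width(eye),
         mrd1_mm = m90,
         peak_temporal_offset_mm = pk$peak_temporal_offset_mm,
         peak_height_mm = pk$peak_height_mm,
         fissure_obliquity_deg = fissure_obliquity(eye),
         mpld = profile,
         tn_ratios = tn_ratios(profile, total = ratio_total)),
    class = "eyelid_metrics"
  )
}

#' @export
print.eyelid_metrics <- function(x, ...) {
  cat(sprintf("Eyelid metrics: subject %s, rater %s, %s\n",
              x$subject_id, x$rater_id, x$laterality))
  cat(sprintf("  eye width      %6.2f mm\n", x$eye_width_mm))
  cat(sprintf("  MRD1           %6.2f mm\n", x$mrd1_mm))
  cat(sprintf("  peak offset    %6.2f mm temporal\n", x$peak_temporal_offset_mm))
  cat(sprintf("  peak height    %6.2f mm\n", x$peak_height_mm))
  cat(sprintf("  obliquity      %6.2f deg\n", x$fissure_obliquity_deg))
  print(x$mpld)
  cat("T:N ratios:\n")
  print(round(x$tn_ratios, 3))
  invisible(x)
}

#' Flatten eyelid metrics to a one-row data frame
#'
#' Wide layout: identifiers, the five scalar metrics, one `mpld_<angle>`
#' column per profile angle, the six pair ratios and `ratio_total`.
#'
#' @param x An `eyelid_metrics` object.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A one-row `data.frame`.
#' @export
as.data.frame.eyelid_metrics <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  angles <- attr(x$mpld, "angles")
  mp <- as.list(unclass(x$mpld))
  names(mp) <- sprintf("mpld_%d", angles)
  out <- c(
    list(subject_id = x$subject_id,
         rater_id = x$rater_id,
         laterality = x$laterality,
         eye_width_mm = x$eye_width_mm,
         mrd1_mm = x$mrd1_mm,
         peak_temporal_offset_mm = x$peak_temporal_offset_mm,
         peak_height_mm = x$peak_height_mm,
         fissure_obliquity_deg = x$fissure_obliquity_deg),
    mp,
    as.list(unclass(x$tn_ratios))
  )
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Combine a list of eyelid metrics into a table
#'
#' @param metrics A list of `eyelid_metrics` objects (or a single one).
#' @return A `data.frame` with one row per eye.
#' @export
metrics_table <- function(metrics) {
  if (inherits(metrics, "eyelid_metrics")) metrics <- list(metrics)
  if (!length(metrics) ||
      !all(vapply(metrics, inherits, logical(1), "eyelid_metrics"))) {
    stop_validation("metrics must be a non-empty list of eyelid_metrics")
  }
  do.call(rbind, lapply(metrics, as.data.frame))
}
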