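## Calibration and frame normalization. Raw landmark files stay faithful to
## the digitization tool (image pixels, y pointing down); every geometric
## convention -- mm scaling, pupil origin, anatomical y-up, temporal/nasal
## mirroring, medial-first control point order -- is applied in exactly one
## place, normalize_eye(), and undone in exactly one place, denormalize_eye().

#' Raw per-eye landmark set
#'
#' Bundles one eye's digitized landmarks in image pixel coordinates
#' (origin top-left, y increasing downward): the four Bezier points traced
#' along the upper lid margin, the two limbus points marking the horizontal
#' white-to-white corneal diameter, the pupil centre, and laterality.
#'
#' @param bezier_px 4 x 2 numeric matrix of Bezier points in digitization
#'   order (rows: endpoint, control, control, endpoint). The two endpoints
#'   must lie on opposite horizontal sides of the pupil.
#' @param limbus_a_px,limbus_b_px Length-2 points on the nasal and temporal
#'   corneal limbus (order irrelevant), spanning the corneal diameter.
#' @param pupil_px Length-2 pupil centre.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param subject_id,rater_id Identifier strings carried through to outputs.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(bezier_px, limbus_a_px, limbus_b_px, pupil_px,
                         laterality, subject_id = "S1", rater_id = "R1") {
  bezier_px <- as.matrix(bezier_px)
  if (!is.numeric(bezier_px) || !all(dim(bezier_px) == c(4L, 2L)) ||
      !all(is.finite(bezier_px))) {
    stop_validation("bezier_px must be a finite numeric 4 x 2 matrix")
  }
  for (nm in c("limbus_a_px", "limbus_b_px", "pupil_px")) {
    p <- get(nm)
    if (!is_point(p)) stop_validation(sprintf("%s must be a finite (x, y) point", nm))
  }
  if (any(bezier_px < 0) || any(c(limbus_a_px, limbus_b_px, pupil_px) < 0)) {
    stop_validation("pixel coordinates must be non-negative")
  }
  if (all(limbus_a_px == limbus_b_px)) {
    stop_validation("limbus points coincide: corneal diameter undefined")
  }
  if (!is.character(laterality) || length(laterality) != 1L ||
      !laterality %in% c("OD", "OS")) {
    stop_validation("laterality must be \"OD\" or \"OS\"")
  }
  side <- sign(bezier_px[c(1L, 4L), 1] - pupil_px[1])
  if (any(side == 0) || side[1] == side[2]) {
    stop_validation("Bezier endpoints must lie on opposite horizontal sides of the pupil")
  }
  dimnames(bezier_px) <- list(c("p0", "p1", "p2", "p3"), c("x", "y"))
  structure(
    list(bezier_px = bezier_px,
         limbus_a_px = as.numeric(limbus_a_px),
         limbus_b_px = as.numeric(limbus_b_px),
         pupil_px = as.numeric(pupil_px),
         laterality = laterality,
         subject_id = as.character(subject_id),
         rater_id = as.character(rater_id)),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set: subject %s, rater %s, %s\n",
              x$subject_id, x$rater_id, x$laterality))
  print(x$bezier_px)
  cat(sprintf("limbus: (%.1f, %.1f) -- (%.1f, %.1f) px; pupil: (%.1f, %.1f) px\n",
              x$limbus_a_px[1], x$limbus_a_px[2],
              x$limbus_b_px[1], x$limbus_b_px[2],
              x$pupil_px[1], x$pupil_px[2]))
  invisible(x)
}

#' Pixel-to-millimetre scale from the corneal diameter
#'
#' Photogrammetric calibration: the horizontal white-to-white corneal
#' diameter is assumed to be a fixed anatomical length (12.0 mm by
#' default), so the scale is that length divided by the pixel distance
#' between the two limbus points.
#'
#' @param limbus_a_px,limbus_b_px Length-2 limbus points in pixels.
#' @param corneal_diameter_mm Assumed white-to-white diameter in mm.
#' @return Scale in mm per pixel.
#' @export
compute_scale <- function(limbus_a_px, limbus_b_px, corneal_diameter_mm = 12) {
  if (!is_point(limbus_a_px) || !is_point(limbus_b_px)) {
    stop_validation("limbus points must be finite (x, y) pairs")
  }
  if (!is.numeric(corneal_diameter_mm) || corneal_diameter_mm <= 0) {
    stop_validation("corneal_diameter_mm must be positive")
  }
  d <- sqrt(sum((limbus_a_px - limbus_b_px)^2))
  if (d == 0) stop_validation("limbus points coincide: cannot calibrate")
  corneal_diameter_mm / d
}

## TRUE when the image x axis must be flipped so nasal lands on +x.
## "viewer": standard non-mirrored photograph, the subject's nose is to the
## viewer's right of an OD eye (no flip) and to the left of an OS eye (flip).
needs_mirror <- function(laterality, mirror_policy) {
  switch(mirror_policy,
         viewer   = laterality == "OS",
         mirrored = laterality == "OD",
         none     = FALSE,
         stop_validation(sprintf("unknown mirror policy \"%s\"", mirror_policy)))
}

#' Normalize an eye into the canonical anatomical frame
#'
#' Converts raw pixel landmarks into the frame in which every metric is
#' defined: origin at the pupil centre, millimetre units via
#' [compute_scale()], y pointing up (the image vertical axis is flipped),
#' and the horizontal axis mirrored per laterality so that nasal is always
#' +x and temporal always -x. Control points are reordered so that `p0` is
#' the medial (nasal) endpoint.
#'
#' The angular grid of the MPLD profile then reads 0 degrees = nasal,
#' 90 = superior, 180 = temporal for every eye regardless of laterality.
#'
#' @param landmarks A [landmark_set()].
#' @param corneal_diameter_mm Calibration constant, mm (default 12.0).
#' @param mirror_policy How laterality maps to an x flip. `"viewer"`
#'   (default) assumes a standard non-mirrored photograph: OS is flipped,
#'   OD is not. `"mirrored"` is the reverse (for mirrored captures);
#'   `"none"` never flips.
#' @return An object of class `normalized_eye` with elements `curve`
#'   (a mm-frame [control_polygon()]), `scale_mm_per_px`, `laterality`,
#'   `subject_id`, `rater_id`, plus the bookkeeping needed by
#'   [denormalize_eye()].
#' @export
normalize_eye <- function(landmarks, corneal_diameter_mm = 12,
                          mirror_policy = c("viewer", "mirrored", "none")) {
  if (!inherits(landmarks, "landmark_set")) {
    stop_validation("landmarks must be a landmark_set")
  }
  mirror_policy <- match.arg(mirror_policy)
  scale <- compute_scale(landmarks$limbus_a_px, landmarks$limbus_b_px,
                         corneal_diameter_mm)
  rel <- sweep(landmarks$bezier_px, 2, landmarks$pupil_px)
  xy <- cbind(x = rel[, 1] * scale, y = -rel[, 2] * scale)
  flip_x <- needs_mirror(landmarks$laterality, mirror_policy)
  if (flip_x) xy[, 1] <- -xy[, 1]
  reversed <- xy[1, 1] < xy[4, 1]
  if (reversed) xy <- xy[4:1, , drop = FALSE]
  if (!(xy[1, 1] > 0 && xy[4, 1] < 0)) {
    stop_validation(paste0(
      "orientation error for subject ", landmarks$subject_id,
      ": endpoints do not straddle the pupil after normalization"))
  }
  structure(
    list(curve = as_control_polygon(xy, frame = "mm"),
         scale_mm_per_px = scale,
         laterality = landmarks$laterality,
         subject_id = landmarks$subject_id,
         rater_id = landmarks$rater_id,
         corneal_diameter_mm = corneal_diameter_mm,
         mirror_policy = mirror_policy,
         flip_x = flip_x,
         reversed = reversed,
         pupil_px = landmarks$pupil_px,
         limbus_a_px = landmarks$limbus_a_px,
         limbus_b_px = landmarks$limbus_b_px),
    class = "normalized_eye"
  )
}

#' @export
print.normalized_eye <- function(x, ...) {
  cat(sprintf("Normalized eye: subject %s, rater %s, %s (%.4f mm/px)\n",
              x$subject_id, x$rater_id, x$laterality, x$scale_mm_per_px))
  print(x$curve)
  invisible(x)
}

#' Invert the frame normalization
#'
#' Maps a [normalize_eye()] result back to the raw pixel landmarks it came
#' from (digitization order, image y-down). Exact inverse up to floating
#' point round-off; used for round-trip validation and for writing
#' synthetic eyes in the raw file schema.
#'
#' @param eye A `normalized_eye`.
#' @return A [landmark_set()].
#' @export
denormalize_eye <- function(eye) {
  if (!inherits(eye, "normalized_eye")) {
    stop_validation("eye must be a normalized_eye")
  }
  xy <- unclass(eye$curve)
  if (eye$reversed) xy <- xy[4:1, , drop = FALSE]
  if (eye$flip_x) xy[, 1] <- -xy[, 1]
  px <- cbind(eye$pupil_px[1] + xy[, 1] / eye$scale_mm_per_px,
              eye$pupil_px[2] - xy[, 2] / eye$scale_mm_per_px)
  landmark_set(px, eye$limbus_a_px, eye$limbus_b_px, eye$pupil_px,
               eye$laterality, eye$subject_id, eye$rater_id)
}
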