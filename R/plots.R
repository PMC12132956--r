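## Base-graphics figures: the Bland-Altman agreement plot and the polar
## contour overlay (eyelid curves drawn around the pupil origin with the
## radial MPLD grid).

#' Bland-Altman plot
#'
#' Plots per-pair differences against per-pair means with the bias line and
#' the 95% limits of agreement.
#'
#' @param x A [bland_altman()] result.
#' @param xlab,ylab,main Axis and title labels.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman <- function(x, xlab = "Mean of raters (mm)",
                              ylab = "Difference (mm)",
                              main = "Bland-Altman agreement", ...) {
  graphics::plot(x$means, x$diffs, pch = 19, col = "grey30",
                 xlab = xlab, ylab = ylab, main = main, ...)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Overlay eyelid contours in the pupil-centred frame
#'
#' Draws one or more normalized eyelid curves around the pupil origin,
#' with the 13 radial MPLD directions as faint spokes and the corneal
#' circle (12 mm diameter by default) for anatomical reference.
#'
#' @param eyes A `normalized_eye` or list of them.
#' @param cols Line colours, recycled over the eyes.
#' @param corneal_diameter_mm Diameter of the reference corneal circle;
#'   `NULL` suppresses it.
#' @param main Plot title.
#' @return The input, invisibly.
#' @export
plot_contours <- function(eyes, cols = NULL, corneal_diameter_mm = 12,
                          main = "Upper eyelid contours") {
  if (inherits(eyes, "normalized_eye")) eyes <- list(eyes)
  stopifnot(all(vapply(eyes, inherits, logical(1), "normalized_eye")))
  if (is.null(cols)) cols <- grDevices::hcl.colors(max(2L, length(eyes)), "Dark 2")
  tseq <- seq(0, 1, length.out = 200)
  pts <- lapply(eyes, function(e) bezier_point(e$curve, tseq))
  xr <- range(vapply(pts, function(p) range(p[, 1]), numeric(2)), 0)
  yr <- range(vapply(pts, function(p) range(p[, 2]), numeric(2)), 0, -6)
  graphics::plot(NA, xlim = rev(xr), ylim = yr, asp = 1,
                 xlab = "nasal  <-  x (mm)  ->  temporal (reversed axis)",
                 ylab = "y (mm)", main = main)
  for (a in mpld_angles()) {
    graphics::segments(0, 0, 20 * cospi(a / 180), 20 * sinpi(a / 180),
                       col = "grey85")
  }
  if (!is.null(corneal_diameter_mm)) {
    th <- seq(0, 2 * pi, length.out = 181)
    r <- corneal_diameter_mm / 2
    graphics::lines(r * cos(th), r * sin(th), col = "grey60", lty = 3)
  }
  graphics::points(0, 0, pch = 19)
  for (i in seq_along(eyes)) {
    graphics::lines(pts[[i]], col = cols[(i - 1L) %% length(cols) + 1L], lwd = 2)
  }
  invisible(eyes)
}
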