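## Cubic Bezier geometry: evaluation, extremum finding, ray intersection and
## least-squares fitting. Everything downstream (MRD1, MPLD, contour peak)
## reduces to these four operations, so they are exact where exactness is
## cheap: the peak comes from the quadratic roots of y'(t), ray hits from the
## cubic roots of the ray-alignment polynomial.

#' Cubic Bezier control polygon
#'
#' Container for the four control points of a cubic Bezier eyelid margin
#' curve. By canonical convention `p0` is the medial (nasal) endpoint and
#' `p3` the lateral (temporal) endpoint; [normalize_eye()] is responsible
#' for establishing that order. The curve is
#' \deqn{B(t) = (1-t)^3 p_0 + 3(1-t)^2 t\, p_1 + 3(1-t) t^2 p_2 + t^3 p_3,
#'   \quad t \in [0, 1].}
#'
#' @param p0,p1,p2,p3 Numeric length-2 points `(x, y)`. `p0` and `p3` are
#'   the on-curve endpoints, `p1` and `p2` the interior control points.
#' @param frame Coordinate frame tag: `"mm"` for the calibrated anatomical
#'   frame or `"px"` for raw image pixels.
#' @return An object of class `control_polygon`: a 4 x 2 matrix of control
#'   points with a `frame` attribute.
#' @examples
#' cp <- control_polygon(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
#' bezier_point(cp, 0.5)
#' @export
control_polygon <- function(p0, p1, p2, p3, frame = c("mm", "px")) {
  frame <- match.arg(frame)
  pts <- list(p0, p1, p2, p3)
  ok <- vapply(pts, is_point, logical(1))
  if (!all(ok)) {
    stop_validation("control points must be finite numeric (x, y) pairs")
  }
  P <- rbind(p0, p1, p2, p3)
  dimnames(P) <- list(c("p0", "p1", "p2", "p3"), c("x", "y"))
  if (all(P[1, ] == P[4, ])) {
    stop_validation("degenerate control polygon: p0 equals p3")
  }
  structure(P, frame = frame, class = "control_polygon")
}

#' @export
print.control_polygon <- function(x, ...) {
  cat("Cubic Bezier control polygon [", attr(x, "frame"), "]\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

as_control_polygon <- function(P, frame = "mm") {
  control_polygon(P[1, ], P[2, ], P[3, ], P[4, ], frame = frame)
}

## Power-basis coefficients, ascending order: B(t) = c0 + c1 t + c2 t^2 + c3 t^3
## (per coordinate). Exact re-expression of the Bernstein form.
bezier_power_coefs <- function(curve) {
  P <- unclass(curve)
  c0 <- P[1, ]
  c1 <- 3 * (P[2, ] - P[1, ])
  c2 <- 3 * (P[1, ] - 2 * P[2, ] + P[3, ])
  c3 <- -P[1, ] + 3 * P[2, ] - 3 * P[3, ] + P[4, ]
  list(x = c(c0[1], c1[1], c2[1], c3[1]),
       y = c(c0[2], c1[2], c2[2], c3[2]))
}

#' Evaluate a cubic Bezier curve
#'
#' Evaluates the curve at parameter values `t` using the Bernstein basis,
#' which interpolates the endpoints exactly: `B(0) = p0`, `B(1) = p3`.
#'
#' @param curve A [control_polygon()].
#' @param t Numeric vector of parameter values in `[0, 1]`.
#' @return A `length(t)` x 2 matrix of curve points (columns `x`, `y`).
#' @export
bezier_point <- function(curve, t) {
  stopifnot(inherits(curve, "control_polygon"))
  if (!is.numeric(t) || anyNA(t) || any(t < 0 | t > 1)) {
    stop_validation("curve parameter t must lie in [0, 1]")
  }
  P <- unclass(curve)
  s <- 1 - t
  b0 <- s^3
  b1 <- 3 * s^2 * t
  b2 <- 3 * s * t^2
  b3 <- t^3
  out <- cbind(
    x = b0 * P[1, 1] + b1 * P[2, 1] + b2 * P[3, 1] + b3 * P[4, 1],
    y = b0 * P[1, 2] + b1 * P[2, 2] + b2 * P[3, 2] + b3 * P[4, 2]
  )
  out
}

## Real roots of a polynomial given ascending coefficients, via the
## companion matrix (polyroot). Imaginary parts below `im_tol` are treated
## as real. Returns numeric(0) for the zero polynomial.
real_poly_roots <- function(coefs, im_tol = 1e-9) {
  scale <- max(abs(coefs))
  if (scale == 0) return(numeric(0))
  keep <- which(abs(coefs) > scale * 1e-14)
  deg <- if (length(keep)) max(keep) - 1L else 0L
  if (deg == 0L) return(numeric(0))
  r <- polyroot(coefs[seq_len(deg + 1L)])
  Re(r[abs(Im(r)) < im_tol])
}

poly_eval <- function(coefs, t) {
  out <- 0
  for (k in rev(seq_along(coefs))) out <- out * t + coefs[k]
  out
}

#' Contour peak of a cubic Bezier curve
#'
#' Finds the global maximum of the y-component of the curve over
#' `t` in `[0, 1]` analytically: `y'(t)` is a quadratic, so the candidate
#' set is its real roots inside the interval plus the two endpoints. Ties
#' (flat maxima) are broken toward the smaller `t`, making the output
#' deterministic.
#'
#' @param curve A [control_polygon()].
#' @return A list with `t` (maximizing parameter) and `point` (named
#'   length-2 numeric, the curve point at the peak).
#' @export
bezier_peak <- function(curve) {
  stopifnot(inherits(curve, "control_polygon"))
  cf <- bezier_power_coefs(curve)
  ## y'(t) = c1 + 2 c2 t + 3 c3 t^2
  dy <- c(cf$y[2], 2 * cf$y[3], 3 * cf$y[4])
  crit <- real_poly_roots(dy)
  crit <- crit[crit > 0 & crit < 1]
  cand <- sort(unique(c(0, crit, 1)))
  yv <- poly_eval(cf$y, cand)
  tol <- 1e-10 * max(1, max(abs(yv)))
  best <- cand[which(yv >= max(yv) - tol)[1]]
  pt <- drop(bezier_point(curve, best))
  list(t = best, point = pt)
}

#' Intersection of a pupil-centred ray with a Bezier curve
#'
#' Casts a ray from the origin (the pupil centre in the normalized frame)
#' at `theta` degrees, with 0 along +x (nasal), 90 straight up and 180
#' along -x (temporal), and intersects it with the curve. Alignment with
#' the ray means `sin(theta) x(t) - cos(theta) y(t) = 0`, a cubic in `t`
#' solved via the companion matrix; admissible roots have `t` in `[0, 1]`
#' and non-negative radial coordinate
#' `r = x(t) cos(theta) + y(t) sin(theta)`. The smallest admissible `r` is
#' returned: the first crossing of the lid margin seen from the pupil is
#' the anatomical mid-pupil lid distance (MPLD).
#'
#' A ray that never meets the curve is not an error: the result carries
#' `r = NA` (for example, a horizontal ray misses a lid arch that stays
#' strictly above the pupil line).
#'
#' @param curve A [control_polygon()] in a pupil-origin frame.
#' @param theta Ray angle in degrees, in `[0, 180]`.
#' @return A list with `r` (distance from origin, `NA` when the ray misses)
#'   and `t` (curve parameter of the hit, `NA` when missing).
#' @export
ray_intersection <- function(curve, theta) {
  stopifnot(inherits(curve, "control_polygon"))
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 180) {
    stop_validation("ray angle theta must be a single value in [0, 180] degrees")
  }
  s <- sinpi(theta / 180)
  co <- cospi(theta / 180)
  cf <- bezier_power_coefs(curve)
  k <- s * cf$x - co * cf$y
  scale <- max(abs(k))
  radial <- function(t) poly_eval(cf$x, t) * co + poly_eval(cf$y, t) * s
  if (scale < 1e-12 * max(1, max(abs(cf$x), abs(cf$y)))) {
    ## Degenerate: the whole curve lies on the ray's line. The nearest
    ## admissible point minimizes the (cubic) radial coordinate over [0,1].
    rc <- cf$x * co + cf$y * s
    dr <- c(rc[2], 2 * rc[3], 3 * rc[4])
    cand <- c(0, 1, real_poly_roots(dr))
    cand <- cand[cand >= 0 & cand <= 1]
    rv <- poly_eval(rc, cand)
    ok <- rv >= -1e-9
    if (!any(ok)) return(list(r = NA_real_, t = NA_real_))
    i <- which(ok)[which.min(rv[ok])]
    return(list(r = max(rv[i], 0), t = cand[i]))
  }
  roots <- real_poly_roots(k)
  ## two Newton polish steps on the alignment cubic
  dk <- c(k[2], 2 * k[3], 3 * k[4])
  for (it in 1:2) {
    f <- poly_eval(k, roots)
    df <- poly_eval(dk, roots)
    step <- ifelse(abs(df) > 0, f / df, 0)
    roots <- roots - step
  }
  roots <- roots[roots >= -1e-9 & roots <= 1 + 1e-9]
  if (!length(roots)) return(list(r = NA_real_, t = NA_real_))
  roots <- pmin(pmax(roots, 0), 1)
  rv <- radial(roots)
  ok <- rv >= -1e-9
  if (!any(ok)) return(list(r = NA_real_, t = NA_real_))
  i <- which(ok)[which.min(rv[ok])]
  list(r = max(rv[i], 0), t = roots[i])
}

#' Least-squares fit of a cubic Bezier to ordered samples
#'
#' Fits a cubic Bezier to an ordered polyline of points by chord-length
#' parameterization followed by linear least squares on the two interior
#' control points. The endpoints are fixed to `endpoints` when given,
#' otherwise to the first and last sample. No reparameterization iterations
#' are performed, so the fit is deterministic.
#'
#' Chord-length parameterization is an approximation: samples of an exact
#' cubic are reproduced exactly only when the sample parameters equal the
#' chord-length fractions, which a curve of non-constant speed does not
#' satisfy. When the generating parameters are known (as for digitizers
#' that report them, or in validation), pass them via `params` and the
#' least-squares solve recovers an exact cubic to machine precision.
#'
#' @param points An n x 2 numeric matrix (n >= 4) of ordered samples.
#' @param endpoints Optional 2 x 2 matrix (rows `p0`, `p3`) of fixed
#'   endpoints.
#' @param params Optional length-n non-decreasing parameter vector in
#'   `[0, 1]` overriding the chord-length parameterization.
#' @param frame Frame tag for the fitted polygon.
#' @return A [control_polygon()] with attribute `rms`, the root-mean-square
#'   residual of the samples at their fit parameters.
#' @export
fit_bezier <- function(points, endpoints = NULL, params = NULL,
                       frame = c("mm", "px")) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L || anyNA(points)) {
    stop_validation("points must be a numeric n x 2 matrix without NAs")
  }
  n <- nrow(points)
  if (n < 4L) {
    stop_validation("fitting a cubic Bezier requires at least 4 points")
  }
  if (is.null(params)) {
    seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                           points[-n, , drop = FALSE])^2))
    total <- sum(seg)
    if (total == 0) stop_validation("all points coincide; cannot parameterize")
    u <- c(0, cumsum(seg)) / total
  } else {
    if (!is.numeric(params) || length(params) != n || anyNA(params) ||
        any(params < 0 | params > 1) || is.unsorted(params)) {
      stop_validation("params must be a non-decreasing length-n vector in [0, 1]")
    }
    u <- params
  }
  if (is.null(endpoints)) {
    p0 <- points[1, ]
    p3 <- points[n, ]
  } else {
    endpoints <- as.matrix(endpoints)
    if (!all(dim(endpoints) == c(2L, 2L)) || anyNA(endpoints)) {
      stop_validation("endpoints must be a 2 x 2 matrix (rows p0, p3)")
    }
    p0 <- endpoints[1, ]
    p3 <- endpoints[2, ]
  }
  s <- 1 - u
  B <- cbind(s^3, 3 * s^2 * u, 3 * s * u^2, u^3)
  rhs <- points - outer(B[, 1], p0) - outer(B[, 4], p3)
  A <- B[, 2:3, drop = FALSE]
  qrA <- qr(A)
  if (qrA$rank < 2L) {
    stop_validation("rank-deficient fit: samples do not constrain the interior control points")
  }
  interior <- qr.coef(qrA, rhs)   # 2 x 2: rows p1, p2
  cp <- control_polygon(p0, interior[1, ], interior[2, ], p3, frame = frame)
  resid <- points - bezier_point(cp, u)
  attr(cp, "rms") <- sqrt(mean(rowSums(resid^2)))
  cp
}
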