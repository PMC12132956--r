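# Independent numerical oracles used to cross-check the analytic geometry.
# They deliberately avoid the implementation's code paths: curve points by
# de Casteljau subdivision, the peak by dense grid search, ray hits by a
# sign-change scan with bisection refinement.

decasteljau_point <- function(P, t) {
  while (nrow(P) > 1) {
    P <- (1 - t) * P[-nrow(P), , drop = FALSE] + t * P[-1, , drop = FALSE]
  }
  drop(P)
}

bernstein_eval <- function(P, t) {
  s <- 1 - t
  cbind(s^3 * P[1, 1] + 3 * s^2 * t * P[2, 1] + 3 * s * t^2 * P[3, 1] + t^3 * P[4, 1],
        s^3 * P[1, 2] + 3 * s^2 * t * P[2, 2] + 3 * s * t^2 * P[3, 2] + t^3 * P[4, 2])
}

grid_peak_oracle <- function(cp, n = 2e5) {
  P <- unclass(cp)
  t <- seq(0, 1, length.out = n)
  xy <- bernstein_eval(P, t)
  i <- which.max(xy[, 2])
  list(t = t[i], x = xy[i, 1], y = xy[i, 2])
}

# Scan the curve for sign changes of the ray-alignment function, refine each
# bracket by bisection, then pick the admissible hit with smallest radius.
scan_ray_oracle <- function(cp, theta, n = 5e4, grid = NULL) {
  P <- unclass(cp)
  s <- sinpi(theta / 180)
  co <- cospi(theta / 180)
  if (is.null(grid)) {
    t <- seq(0, 1, length.out = n)
    xy <- bernstein_eval(P, t)
  } else {
    t <- grid$t
    xy <- grid$xy
  }
  f <- s * xy[, 1] - co * xy[, 2]
  m <- length(t)
  idx <- which(sign(f[-1]) * sign(f[-m]) < 0)
  roots <- t[f == 0]
  for (i in idx) {
    lo <- t[i]; hi <- t[i + 1]; flo <- f[i]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      pm <- bernstein_eval(P, mid)
      fm <- s * pm[1] - co * pm[2]
      if (sign(fm) == sign(flo) && fm != 0) {
        lo <- mid; flo <- fm
      } else {
        hi <- mid
      }
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  if (!length(roots)) return(list(r = NA_real_, t = NA_real_))
  xy2 <- bernstein_eval(P, roots)
  rr <- co * xy2[, 1] + s * xy2[, 2]
  ok <- rr >= -1e-9
  if (!any(ok)) return(list(r = NA_real_, t = NA_real_))
  i <- which(ok)[which.min(rr[ok])]
  list(r = max(rr[i], 0), t = roots[i])
}

# Random lid-like curve in a pupil-origin frame: endpoints straddle the
# origin horizontally, interior control points pull the arch upward.
random_lid_curve <- function() {
  p0 <- c(runif(1, 8, 14), runif(1, -6, 0))
  p3 <- c(-runif(1, 8, 14), runif(1, -6, 1))
  p1 <- c(runif(1, -4, 10), runif(1, 1, 9))
  p2 <- c(runif(1, -10, 4), runif(1, 1, 9))
  control_polygon(p0, p1, p2, p3)
}

# Fully generic random cubic (no lid structure), for convex-hull and
# peak-oracle properties.
random_cubic <- function(lim = 10) {
  pts <- matrix(runif(8, -lim, lim), 4, 2)
  control_polygon(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
}
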