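# Cubic Bezier core: evaluation, peak, ray intersection, fitting.

test_that("bezier_point matches closed-form and de Casteljau values", {
  sym <- control_polygon(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  expect_equal(drop(bezier_point(sym, 0.5)), c(x = 0.5, y = 0.75))

  # endpoint interpolation is exact for arbitrary curves
  set.seed(11)
  for (i in 1:20) {
    cp <- random_cubic()
    P <- unclass(cp)
    expect_identical(drop(bezier_point(cp, 0)), c(x = P[1, 1], y = P[1, 2]))
    expect_identical(drop(bezier_point(cp, 1)), c(x = P[4, 1], y = P[4, 2]))
  }

  # frozen de Casteljau oracle value
  cp <- control_polygon(c(0, 0), c(1, 2), c(2, -1), c(3, 1))
  expect_equal(drop(bezier_point(cp, 0.3)), c(x = 0.9, y = 0.72),
               tolerance = 1e-12)
  # and live agreement with the oracle at random parameters
  set.seed(12)
  for (t in runif(20)) {
    expect_equal(unname(drop(bezier_point(cp, t))),
                 unname(decasteljau_point(unclass(cp), t)), tolerance = 1e-12)
  }

  expect_error(bezier_point(cp, 1.2), class = "bezlid_validation_error")
  expect_error(bezier_point(cp, -0.1), class = "bezlid_validation_error")
})

test_that("curve points stay inside the control polygon convex hull", {
  set.seed(21)
  for (i in 1:50) {
    cp <- random_cubic()
    P <- unclass(cp)
    xy <- bezier_point(cp, seq(0, 1, length.out = 50))
    # axis-aligned bounding box of the hull contains the curve
    expect_true(all(xy[, 1] >= min(P[, 1]) - 1e-12 &
                      xy[, 1] <= max(P[, 1]) + 1e-12))
    expect_true(all(xy[, 2] >= min(P[, 2]) - 1e-12 &
                      xy[, 2] <= max(P[, 2]) + 1e-12))
  }
})

test_that("bezier_peak finds the global y maximum analytically", {
  sym <- control_polygon(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  pk <- bezier_peak(sym)
  expect_equal(pk$t, 0.5)
  expect_equal(unname(pk$point), c(0.5, 0.75))

  # flat curve: peak y = c, tie broken toward t = 0
  flat <- control_polygon(c(0, 2), c(1, 2), c(2, 2), c(3, 2))
  pk <- bezier_peak(flat)
  expect_equal(pk$point[["y"]], 2)
  expect_equal(pk$t, 0)

  # frozen dense-grid oracle value (2e6-point grid)
  cp <- control_polygon(c(0, 0), c(2, 6), c(8, 4), c(12, 1))
  pk <- bezier_peak(cp)
  expect_equal(pk$t, 0.4727975, tolerance = 1e-6)
  expect_equal(pk$point[["y"]], 3.8852712945, tolerance = 1e-6)
  expect_equal(pk$point[["x"]], 4.8851069532, tolerance = 1e-5)

  # property: matches grid search within 1e-6 on y for random curves
  set.seed(31)
  for (i in 1:100) {
    cp <- random_cubic()
    pk <- bezier_peak(cp)
    gr <- grid_peak_oracle(cp)
    expect_lt(abs(pk$point[["y"]] - gr$y), 1e-6)
    expect_gte(pk$point[["y"]], gr$y - 1e-12)  # analytic >= any sampled y
  }
})

test_that("ray_intersection solves the alignment cubic and picks the nearest hit", {
  arch <- control_polygon(c(-0.5, 0), c(-0.5, 1), c(0.5, 1), c(0.5, 0))
  hit <- ray_intersection(arch, 90)
  expect_equal(hit$r, 0.75)
  expect_equal(hit$t, 0.5)
  hit0 <- ray_intersection(arch, 0)
  expect_equal(hit0$r, 0.5)

  # frozen scan+bisection oracle value
  cp <- control_polygon(c(-12, -1), c(-6, 6), c(4, 7), c(12, 2))
  hit <- ray_intersection(cp, 45)
  expect_equal(hit$r, 6.806232261444, tolerance = 1e-8)
  expect_equal(hit$t, 0.715045775503, tolerance = 1e-8)

  # a lid arch strictly above the pupil line misses horizontal rays
  high <- control_polygon(c(10, 2), c(3, 6), c(-3, 6), c(-10, 2))
  expect_true(is.na(ray_intersection(high, 0)$r))
  expect_true(is.na(ray_intersection(high, 180)$r))
  expect_false(is.na(ray_intersection(high, 90)$r))

  expect_error(ray_intersection(cp, 190), class = "bezlid_validation_error")
  expect_error(ray_intersection(cp, -5), class = "bezlid_validation_error")
})

test_that("ray_intersection agrees with the dense-sampling oracle on random lids", {
  set.seed(41)
  angles <- mpld_angles()
  for (i in 1:60) {
    cp <- random_lid_curve()
    for (a in angles) {
      hit <- ray_intersection(cp, a)
      orc <- scan_ray_oracle(cp, a)
      expect_identical(is.na(hit$r), is.na(orc$r))
      if (!is.na(hit$r)) expect_lt(abs(hit$r - orc$r), 1e-4)
    }
  }
})

test_that("vertical ray hit equals y at the x-root of the curve", {
  set.seed(51)
  for (i in 1:50) {
    cp <- random_lid_curve()
    hit <- ray_intersection(cp, 90)
    # independent route: bracket every root of x(t) on a grid, bisect each,
    # and take the smallest non-negative y among the crossings
    P <- unclass(cp)
    tg <- seq(0, 1, length.out = 2000)
    xg <- bernstein_eval(P, tg)[, 1]
    ys <- c()
    for (j in which(sign(xg[-1]) * sign(xg[-2000]) < 0)) {
      lo <- tg[j]; hi <- tg[j + 1]; flo <- xg[j]
      for (k in 1:60) {
        mid <- (lo + hi) / 2
        fm <- bernstein_eval(P, mid)[, 1]
        if (sign(fm) == sign(flo) && fm != 0) { lo <- mid; flo <- fm } else hi <- mid
      }
      ys <- c(ys, bernstein_eval(P, (lo + hi) / 2)[, 2])
    }
    ys <- ys[ys >= 0]
    if (length(ys)) {
      expect_lt(abs(hit$r - min(ys)), 1e-8)
    } else {
      expect_true(is.na(hit$r))
    }
  }
})

test_that("fit_bezier recovers exact curves and degrades gracefully with noise", {
  set.seed(61)
  # exact recovery: noiseless samples with consistent parameters reproduce
  # the generating interior control points (least-squares identity)
  for (i in 1:10) {
    cp <- random_lid_curve()
    u <- sort(c(0, runif(48), 1))
    pts <- bezier_point(cp, u)
    fit <- fit_bezier(pts, params = u)
    expect_equal(unclass(fit)[2:3, ], unclass(cp)[2:3, ], tolerance = 1e-6)
    expect_lt(attr(fit, "rms"), 1e-9 * max(1, max(abs(unclass(cp)))))
  }

  # chord-length default on samples of a lid-like arch: the parameterization
  # mismatch leaves a small residual, bounded well below anatomical scale
  cp <- control_polygon(c(12.2, -2.6), c(2.9, 8.2), c(-5.9, 7.4), c(-12.8, -0.5))
  pts <- bezier_point(cp, seq(0, 1, length.out = 200))
  fit <- fit_bezier(pts)
  expect_lt(attr(fit, "rms"), 0.3)
  expect_lt(abs(bezier_peak(fit)$point[["y"]] - bezier_peak(cp)$point[["y"]]), 0.3)

  # straight-line samples give collinear control points
  line_pts <- cbind(seq(0, 10, length.out = 30), seq(0, 5, length.out = 30))
  fit <- fit_bezier(line_pts)
  P <- unclass(fit)
  # cross products of consecutive edges vanish
  e1 <- P[2, ] - P[1, ]; e2 <- P[3, ] - P[1, ]; e3 <- P[4, ] - P[1, ]
  expect_lt(abs(e1[1] * e2[2] - e1[2] * e2[1]), 1e-6)
  expect_lt(abs(e1[1] * e3[2] - e1[2] * e3[1]), 1e-6)

  expect_error(fit_bezier(line_pts[1:3, ]), class = "bezlid_validation_error")
  expect_error(fit_bezier(matrix(1, 10, 2)), class = "bezlid_validation_error")
})

test_that("fitting noisy samples recovers the peak height to within the noise scale", {
  set.seed(71)
  truth <- control_polygon(c(12, -2), c(4, 9), c(-7, 8), c(-13, 0))
  h_true <- bezier_peak(truth)$point[["y"]]
  u <- seq(0, 1, length.out = 200)
  clean <- bezier_point(truth, u)
  errs <- replicate(100, {
    pts <- clean + matrix(rnorm(400, 0, 0.05), 200, 2)
    fit <- fit_bezier(pts, params = u)
    abs(bezier_peak(fit)$point[["y"]] - h_true)
  })
  expect_lt(mean(errs), 0.05)
})
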