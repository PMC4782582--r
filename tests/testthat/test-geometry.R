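test_that("point ordering sorts, averages duplicates and picks the longer axis", {
  pts <- cbind(row = c(0, 1, 1, 2), col = c(0, 2, 4, 6))
  pts8 <- rbind(pts, cbind(row = 3:7, col = 8))
  got <- order_points(pts8, axis = "y")
  expect_identical(got$s[1:3], c(0, 1, 2))
  expect_identical(got$f[1:3], c(0, 3, 6))   # duplicates averaged

  # auto axis: vertical-extent-dominant cloud picks y
  set.seed(3)
  cloud <- cbind(row = runif(50, 0, 100), col = runif(50, 0, 10))
  expect_identical(order_points(cloud)$axis, "y")
  expect_identical(order_points(cloud[, 2:1])$axis, "x")

  # random clouds: output strictly increasing, matches group-by means
  for (i in 1:5) {
    p <- cbind(row = sample(0:60, 500, TRUE), col = runif(500, 0, 30))
    o <- order_points(p, axis = "y")
    expect_true(all(diff(o$s) > 0))
    want <- tapply(p[, 2], p[, 1], mean)
    expect_equal(o$f, as.vector(want[order(as.numeric(names(want)))]))
  }

  expect_error(order_points(pts), class = "insufficient_data_error")
})

test_that("polynomial fitting is exact on polynomial data", {
  s <- seq(-3, 3, length.out = 60)
  fit <- fit_polynomial(list(s = s, f = s^2, axis = "y"))
  ev <- eval_fit(fit, seq(-3, 3, length.out = 200))
  expect_lt(max(abs(ev$f - seq(-3, 3, length.out = 200)^2)), 1e-8)

  co <- c(0.3, -1, 0.5, 0.02, -0.004, 3e-4, -2e-5)
  f6 <- drop(outer(s, 0:6, "^") %*% co)
  fit6 <- fit_polynomial(list(s = s, f = f6, axis = "y"))
  expect_lt(fit6$rms_residual, 1e-8)
  # pixel-frame coefficients reproduce the generating polynomial
  expect_equal(fit6$coeffs_pixel, co, tolerance = 1e-6)
})

test_that("least-squares fit matches the normal-equations oracle on noisy data", {
  set.seed(11)
  s <- seq(0, 40, length.out = 200)
  f <- 2 * s + 1 + rnorm(200, 0, 0.1)
  fit <- fit_polynomial(list(s = s, f = f, axis = "y"), degree = 6L)
  sse_fit <- sum((eval_fit(fit, s)$f - f)^2)
  co_oracle <- oracle_polyfit((s - mean(range(s))) / (diff(range(s)) / 2), f, 6)
  u <- (s - mean(range(s))) / (diff(range(s)) / 2)
  sse_oracle <- sum((drop(outer(u, 0:6, "^") %*% co_oracle) - f)^2)
  expect_lt(abs(sse_fit - sse_oracle), 1e-6)
})

test_that("degenerate designs raise informative errors", {
  # too few distinct ordered coordinates
  expect_error(fit_polynomial(list(s = 1:5, f = rnorm(5), axis = "y")),
               class = "insufficient_data_error")
  # s clustered at two locations: rank-deficient design
  expect_error(fit_polynomial(list(s = rep(c(0, 1), 8), f = rnorm(16),
                                   axis = "y")),
               class = "conditioning_error")
})

test_that("curvature analytics: circles, straight lines and parabolas", {
  # circle arcs over 90 degrees: within 1% on the central 80%
  for (R in c(30, 50, 120)) {
    pts <- circle_arc_points(R, 90)
    fit <- fit_polynomial(list(s = pts[, 1], f = pts[, 2], axis = "y"))
    mid <- mean(fit$s_range); half <- diff(fit$s_range) / 2
    grid <- seq(mid - 0.8 * half, mid + 0.8 * half, length.out = 150)
    cv <- curvature(fit, grid)
    expect_lt(max(abs(abs(cv$curvature) - 1 / R)) * R, 0.01)
  }

  # straight line: zero curvature to numerical precision
  fitl <- fit_polynomial(list(s = seq(0, 100, 0.5),
                              f = 0.3 * seq(0, 100, 0.5) + 7, axis = "y"))
  cvl <- curvature(fitl)
  expect_lt(max(abs(cvl$curvature)), 1e-10)

  # parabola f = a s^2: c(0) = 2a exactly
  a <- 0.01
  s <- seq(-40, 40, 0.25)
  fitp <- fit_polynomial(list(s = s, f = a * s^2, axis = "y"))
  c0 <- curvature(fitp, s_grid = c(-1, 0, 1))$curvature[2]
  expect_equal(c0, 2 * a, tolerance = 1e-12)
})

test_that("grids outside the fitted range raise extrapolation errors", {
  fit <- fit_polynomial(list(s = 0:20, f = (0:20)^2 / 10, axis = "y"))
  expect_error(curvature(fit, s_grid = seq(-5, 5, 1)),
               class = "extrapolation_error")
  expect_error(average_curvature(fit, -1, 10), class = "extrapolation_error")
})

test_that("average curvature times arc length equals the tangent rotation", {
  # quarter circle: total rotation pi/2 within 1e-2 rad
  R <- 60
  pts <- circle_arc_points(R, 90)
  fit <- fit_polynomial(list(s = pts[, 1], f = pts[, 2], axis = "y"))
  avg <- average_curvature(fit, fit$s_range[1], fit$s_range[2])
  expect_equal(avg$total_rotation, pi / 2, tolerance = 1e-2)

  # straight segment: rotation and mean curvature are zero
  fitl <- fit_polynomial(list(s = 0:30, f = rep(2, 31) + 0.5 * (0:30),
                              axis = "y"))
  avgl <- average_curvature(fitl, 0, 30)
  expect_equal(avgl$total_rotation, 0, tolerance = 1e-12)
  expect_equal(avgl$kappa_bar, 0, tolerance = 1e-12)

  # quadrature of kappa over arc length equals endpoint tangent difference
  # for every fit (here: a wiggly degree-6 curve)
  set.seed(19)
  s <- seq(0, 120, 0.5)
  f <- 30 + 0.2 * s + 1e-5 * s^3 - 5e-8 * s^4
  fitw <- fit_polynomial(list(s = s, f = f, axis = "y"))
  for (pair in list(c(5, 100), c(20, 60), c(0.5, 119))) {
    avg <- average_curvature(fitw, pair[1], pair[2])
    quad <- integrate(function(ss) {
      ev <- eval_fit(fitw, ss)
      (ev$f2 / (1 + ev$f1^2)^1.5) * sqrt(1 + ev$f1^2)
    }, pair[1], pair[2], rel.tol = 1e-10)$value
    expect_equal(avg$kappa_bar * avg$arc_length, quad, tolerance = 1e-6)
    expect_equal(avg$total_rotation, quad, tolerance = 1e-6)
  }
})

test_that("curvature is frame invariant and scales correctly", {
  pts <- circle_arc_points(75, 80)
  fit <- fit_polynomial(list(s = pts[, 1], f = pts[, 2], axis = "y"))
  grid <- seq(fit$s_range[1] + 5, fit$s_range[2] - 5, length.out = 100)
  base <- curvature(fit, grid)$curvature

  # translation leaves curvature unchanged
  fit_t <- fit_polynomial(list(s = pts[, 1] + 37, f = pts[, 2] - 12,
                               axis = "y"))
  shifted <- curvature(fit_t, grid + 37)$curvature
  expect_lt(max(abs(shifted - base)), 1e-9)

  # uniform scaling by lambda scales curvature by 1/lambda
  lam <- 2.5
  fit_s <- fit_polynomial(list(s = pts[, 1] * lam, f = pts[, 2] * lam,
                               axis = "y"))
  scaled <- curvature(fit_s, grid * lam)$curvature
  expect_lt(max(abs(scaled - base / lam)), 1e-9)

  # reflecting across the s-axis negates the signed curvature exactly
  fit_r <- fit_polynomial(list(s = pts[, 1], f = -pts[, 2], axis = "y"))
  expect_equal(curvature(fit_r, grid)$curvature, -base, tolerance = 1e-12)
})

test_that("flexural rigidity divides moment by curvature and masks zeros", {
  pts <- circle_arc_points(100, 60, n = 300)
  fit <- fit_polynomial(list(s = pts[, 1], f = pts[, 2], axis = "y"))
  cv <- curvature(fit)
  # uniform beam under end moment M0: EI = M0 * R everywhere
  M0 <- 2
  rig <- flexural_rigidity(cv, rep(M0, length(cv$s_grid)))
  expect_true(all(!rig$mask))
  expect_equal(rig$EI[!rig$mask], rep(M0 * 100, sum(!rig$mask)),
               tolerance = 0.01 * M0 * 100, ignore_attr = TRUE)

  # constant curvature 0.5, moment 1: EI = 2 (pure division)
  cv2 <- structure(list(s_grid = 1:10, curvature = rep(0.5, 10), f = 1:10),
                   class = "curvature_profile")
  rig2 <- flexural_rigidity(cv2, rep(1, 10))
  expect_equal(rig2$EI, rep(2, 10))

  # zero curvature masks every position
  cv3 <- structure(list(s_grid = 1:10, curvature = rep(0, 10), f = 1:10),
                   class = "curvature_profile")
  expect_warning(rig3 <- flexural_rigidity(cv3, rep(1, 10)),
                 class = "degenerate_curvature_warning")
  expect_true(all(rig3$mask))
})
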