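test_that("fit_circle recovers exact circles and reports degenerate input", {
  ## circumcircle of 3 points on the unit circle
  th <- c(0.2, 2.1, 4.4)
  f <- fit_circle(cbind(cos(th), sin(th)))
  expect_close(f$center, c(0, 0), 1e-9)
  expect_close(f$radius, 1, 1e-9)
  expect_lt(f$rms_residual, 1e-12)

  ## 200 noiseless samples of R = 11 centred (2, -3)
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  pts <- cbind(2 + 11 * cos(th), -3 + 11 * sin(th))
  f <- fit_circle(pts)
  expect_close(f$center, c(2, -3), 1e-9)
  expect_close(f$radius, 11, 1e-9)
  expect_lt(f$rms_residual, 1e-9)

  expect_error(fit_circle(cbind(1:10, 2 * (1:10) + 1)),
               class = "mpsjc_degenerate_fit")
})

test_that("fit_circle radius is accurate under Gaussian noise (Monte Carlo)", {
  th <- seq(0, 2 * pi, length.out = 200)
  hits <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    pts <- cbind(11 * cos(th) + rnorm(200, 0, 0.1),
                 11 * sin(th) + rnorm(200, 0, 0.1))
    f <- fit_circle(pts)
    if (abs(f$radius - 11) < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("fit_profile round-trips a noiseless two-arc profile", {
  ## recovery is limited by the finite-difference Jacobian of the geometric
  ## least squares (~1e-5 relative); far below any digitisation noise
  prof <- profile_groove(11, -62, -22, 0.8, 0.3)
  pts <- profile_point(prof, seq(-80, 50, length.out = 150))
  f <- fit_profile(pts, template = list(arcs = 3, inception = -62,
                                        termination = -22, trough_frac = 0.3))
  expect_close(f$center, c(0, 0), 5e-5)
  expect_lt(abs(f$radius - 11) / 11, 1e-5)
  expect_lt(abs(f$flattening - 0.8) / 0.8, 1e-4)
  expect_lt(f$rms_residual, 1e-5)
})

test_that("fit_profile recovers the trough position when it is free", {
  prof <- profile_groove(11, -62, -22, 0.8, 0.7)
  pts <- profile_point(prof, seq(-80, 50, length.out = 150))
  f <- fit_profile(pts, template = list(arcs = 3, inception = -62,
                                        termination = -22, trough_frac = 0.4,
                                        fit_trough_frac = TRUE))
  expect_lt(abs(f$trough_frac - 0.7), 0.01)
  expect_lt(abs(f$flattening - 0.8), 0.01)
})

test_that("fit_profile recovers groove flattening under realistic noise", {
  hits <- 0
  n_seeds <- 50
  psis <- seq(-80, 50, length.out = 150)
  prof <- profile_groove(11, -62, -22, 0.8, 0.7)
  clean <- profile_point(prof, psis)
  for (s in 1:n_seeds) {
    set.seed(2000 + s)
    pts <- clean + matrix(rnorm(2 * nrow(clean), 0, 0.005 * 11), ncol = 2)
    f <- tryCatch(
      fit_profile(pts, template = list(arcs = 3, inception = -62,
                                       termination = -22, trough_frac = 0.7)),
      error = function(e) NULL)
    if (!is.null(f) && abs(f$flattening - 0.8) / 0.8 < 0.2) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_seeds)
})

test_that("a two-arc template on pure-circle points degenerates to the circle", {
  th <- seq(-80, 50, length.out = 150)
  pts <- cbind(11 * cos(th * pi / 180), 11 * sin(th * pi / 180))
  f <- fit_profile(pts, template = list(arcs = 3, inception = -62,
                                        termination = -22, trough_frac = 0.3))
  expect_lt(f$flattening, 1e-3)
  expect_close(f$radius, 11, 1e-6)
})

test_that("one-arc templates reduce fit_profile to fit_circle", {
  th <- seq(0, 2 * pi, length.out = 80)
  pts <- cbind(4 + 9 * cos(th), 1 + 9 * sin(th))
  f1 <- fit_profile(pts, template = list(arcs = 1))
  f2 <- fit_circle(pts)
  expect_close(f1$center, f2$center, 1e-12)
  expect_close(f1$radius, f2$radius, 1e-12)
})
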