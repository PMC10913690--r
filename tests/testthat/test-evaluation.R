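test_that("linear least-squares calibration handles the canonical cases", {
  fit <- fit_calibration(c(0.01, 0.02, 0.03), c(100, 150, 200))
  expect_equal(fit$slope, 5000)
  expect_equal(fit$intercept, 50)
  expect_equal(fit$r, 1)

  flat <- fit_calibration(c(0.01, 0.02, 0.03), c(120, 120, 120))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r, 0)

  anti <- fit_calibration(c(0.01, 0.02, 0.03), c(200, 150, 100))
  expect_equal(anti$r, -1)

  expect_error(fit_calibration(rep(0.01, 5), c(1, 2, 3, 4, 5)),
               "degenerate-fit")
  expect_error(fit_calibration(c(0.01, 0.02), c(1, 2)), "insufficient-data")
})

test_that("r is invariant under positive affine transforms of the index", {
  set.seed(3)
  mi <- runif(30); g <- 100 + 500 * mi + rnorm(30, sd = 5)
  r0 <- fit_calibration(mi, g)$r
  r1 <- fit_calibration(3.7 * mi + 0.2, g)$r
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("MARD and RMSE arithmetic and reordering invariance", {
  expect_equal(mard(c(100, 200), c(100, 200)), 0)
  expect_equal(mard(c(100, 200), c(110, 180)), 10)
  expect_equal(mard(100, 150), 50)
  expect_error(mard(c(0, 100), c(1, 1)), "domain error")

  expect_equal(rmse(c(100, 200), c(100, 200)), 0)
  expect_equal(rmse(c(100, 200), c(110, 180)), sqrt(250))
  expect_equal(rmse(100, 120), 20)

  set.seed(4)
  ref <- runif(20, 80, 300); est <- ref + rnorm(20, sd = 20)
  o <- sample(20)
  expect_equal(mard(ref[o], est[o]), mard(ref, est))
  expect_equal(rmse(ref[o], est[o]), rmse(ref, est))
})

test_that("Parkes type-1 zones match hand-derived boundary interpolation", {
  # expected labels derived by linear interpolation of the published
  # vertex table, e.g. at ref 50 the upper boundaries sit at est
  # 71.8 (A/B), 80 (B/C), 125 (C/D), 550 (D/E), so est 350 is zone D
  ref <- c(100, 400, 50, 100, 200, 20, 150, 300, 400, 0, 600)
  est <- c(100, 400, 350, 135, 450, 160, 100, 80, 50, 0, 600)
  expect_equal(parkes_zone(ref, est),
               c("A", "A", "D", "B", "C", "E", "B", "C", "D", "A", "A"))
  expect_error(parkes_zone(650, 100), "domain error")
  expect_error(parkes_zone(100, -1), "domain error")
})

test_that("Parkes zones are total and risk-monotone on [0,600]^2", {
  # coarse rasterization here (acceptance covers 1 mg/dL)
  grid <- seq(0, 600, by = 5)
  risk <- c(A = 0, B = 1, C = 2, D = 3, E = 4)
  for (r in seq(0, 600, by = 60)) {
    z <- parkes_zone(rep(r, length(grid)), grid)
    expect_false(any(is.na(z)))
    rk <- risk[z]
    above <- grid >= r
    expect_true(all(diff(rk[above]) >= 0))
    expect_true(all(diff(rk[!above]) <= 0))
    # the diagonal itself is always zone A
    expect_equal(unname(parkes_zone(r, r)), "A")
  }
})

test_that("session evaluation: perfect agreement and a 10% bias", {
  ser <- data.frame(time_s = seq(0, 3000, by = 60),
                    smoothed = seq(0.01, 0.04, length.out = 51))
  g_perfect <- glucose_series(seq(300, 2700, by = 300),
                              50 + 5000 * interpolate_to(
                                ser$time_s, ser$smoothed,
                                seq(300, 2700, by = 300)))
  res <- evaluate_session(ser, g_perfect)
  expect_equal(unname(res$zone_percent["A"]), 100)
  expect_equal(res$mard, 0, tolerance = 1e-9)
  expect_equal(res$rmse, 0, tolerance = 1e-6)

  # fixed calibration, estimate = 1.10 * reference
  fit <- list(slope = 5500, intercept = 55)
  res2 <- evaluate_session(ser, g_perfect, fit = fit)
  expect_equal(res2$mard, 10, tolerance = 1e-9)

  expect_error(evaluate_session(ser, glucose_series(c(9000, 9100, 9200),
                                                    c(100, 100, 100))),
               "insufficient-data")
})
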