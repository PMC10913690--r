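test_that("arterial saturation is the amplitude ratio", {
  expect_equal(compute_sao2(1, 0), 1.0)
  expect_equal(compute_sao2(0.9, 0.1), 0.9)
  expect_error(compute_sao2(0, 0), "domain error")
  expect_error(compute_sao2(-1, 2), "domain error")
})

test_that("phase delay is wrapped to (-pi, pi] with the lag-positive sign", {
  expect_equal(compute_phase_delay(list(phase_hbo2 = 1.2, phase_hb = 1.2)), 0)
  # brute-force wrap arithmetic: 3.1 - (-3.1) = 6.2 -> 6.2 - 2*pi
  expect_equal(compute_phase_delay(list(phase_hbo2 = 3.1, phase_hb = -3.1)),
               6.2 - 2 * pi, tolerance = 1e-12)
  expect_equal(wrap_phase(pi), pi)
  expect_equal(wrap_phase(-pi), pi)
  expect_equal(wrap_phase(2 * pi), 0)

  # analytic on-bin construction: deoxy delayed by 0.1 rad
  pk <- main_peak(window_spectrum(make_sine_window(dtheta = 0.1)))
  expect_equal(compute_phase_delay(pk), 0.1, tolerance = 1e-3)
  # cross-check by maximizing the cross-correlation lag
  fs <- 2000; f <- 1.25
  tt <- seq(0, 8, by = 1 / fs)
  r <- stats::ccf(sin(2 * pi * f * tt - 0.1), sin(2 * pi * f * tt),
                  lag.max = 200, plot = FALSE)
  lag_s <- r$lag[which.max(r$acf)] / fs
  expect_equal(2 * pi * f * lag_s, 0.1, tolerance = 0.02)  # lag grid quantum
})

test_that("metabolic index formula and saturation factor", {
  expect_equal(metabolic_index(0.90, 0.1), 0.009)
  expect_equal(metabolic_index(1.0, 0.5), 0)
  expect_equal(metabolic_index(0.5, -0.2), 0.05)
  expect_error(metabolic_index(1.2, 0.1), "domain error")
  # saturation factor over the observed 88-92% range
  f <- function(s) s * (1 - s)
  expect_equal(f(0.92), 0.0736)
  expect_equal(f(0.88), 0.1056)
  expect_equal(round(f(0.88) / f(0.92), 1), 1.4)
})

test_that("alpha correction follows the power law and its identities", {
  b1 <- alpha_baseline(0.01, n = 1)
  expect_equal(alpha_correction(0.004, 0.002, b1), 1)       # n = 1: exponent 0
  b05 <- alpha_baseline(0.01, n = 0.5)
  expect_equal(alpha_correction(0.036, 0.004, b05), 0.25)   # 4^(1-2)
  expect_equal(alpha_correction(0.009, 0.001, b05), 1.0)
  expect_true(is.na(alpha_correction(0, 0, b05)))
  expect_error(alpha_baseline(-1), "domain error")
  expect_error(alpha_baseline(0.01, n = 2), "config error")

  expect_equal(corrected_index(0.01, 1.0), 0.01)
  expect_equal(corrected_index(0, 5), 0)
  expect_equal(corrected_index(0.009, 0.25), 0.00225)
})

test_that("MI is scale-invariant in the amplitudes; alpha is not", {
  b <- alpha_baseline(0.01, n = 0.5)
  for (k in c(0.5, 2, 10)) {
    s1 <- compute_sao2(0.008, 0.002)
    s2 <- compute_sao2(k * 0.008, k * 0.002)
    expect_equal(metabolic_index(s2, 0.1), metabolic_index(s1, 0.1))
    expect_false(isTRUE(all.equal(alpha_correction(k * 0.008, k * 0.002, b),
                                  alpha_correction(0.008, 0.002, b))))
  }
})

test_that("deoxy pulsation amplitude: small-angle vs exact two-sinusoid form", {
  # brute-force amplitude of sin(wt - dtheta) - sin(wt) on a dense grid
  brute <- function(dtheta) {
    t <- seq(0, 1, length.out = 200001)
    max(abs(sin(2 * pi * t - dtheta) - sin(2 * pi * t)))
  }
  for (dt in c(0.05, 0.1)) {
    exact <- chb_ac_amplitude(0.9, 0.1, 1, dt, method = "exact")
    direct <- brute(dt) * 0.9 * 0.1 / (0.9 + 0.1)
    expect_equal(exact, direct, tolerance = 1e-8)
    approx <- chb_ac_amplitude(0.9, 0.1, 1, dt, method = "small_angle")
    expect_lt(abs(approx - exact) / exact, 5e-4)
  }
  # small-angle error stays below 0.4% through |dtheta| <= 0.3
  for (dt in seq(0.05, 0.3, by = 0.05)) {
    e <- chb_ac_amplitude(0.5, 0.5, 1, dt, method = "exact")
    a <- chb_ac_amplitude(0.5, 0.5, 1, dt, method = "small_angle")
    expect_lt(abs(a - e) / e, 0.004)
  }
  expect_equal(chb_ac_amplitude(0.9, 0.1, 1, 0), 0)
  expect_equal(chb_ac_amplitude(0.9, 0.1, 1.0, 0.1), 0.009)
  expect_error(chb_ac_amplitude(1, 1, 0, 0.1), "domain error")
})

test_that("ideal measurement time spans 7.2 to 20 seconds", {
  b <- measurement_time_bounds()
  expect_equal(unname(b), c(7.2, 20))
})
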