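test_that("simulation parameters enforce the stated-world constraints", {
  expect_error(simulation_params(), "seed is mandatory")
  expect_error(simulation_params(dtheta = 1.0, seed = 1), "pi/4")
  expect_error(simulation_params(sao2 = 1.2, seed = 1), "config error")
  expect_error(simulation_params(a_sum = 0.5, seed = 1), "5%")
})

test_that("identical seed and parameters give bit-identical records", {
  r1 <- simulate_window(simulation_params(duration_s = 10, seed = 9))$record
  r2 <- simulate_window(simulation_params(duration_s = 10, seed = 9))$record
  expect_identical(r1$channel_a, r2$channel_a)
  expect_identical(r1$channel_b, r2$channel_b)
  r3 <- simulate_window(simulation_params(duration_s = 10, seed = 10))$record
  expect_false(identical(r1$channel_a, r3$channel_a))
})

test_that("forward signals satisfy the path-length conservation law", {
  sim <- simulate_window(default_sim(seed = 2))
  with(sim$truth, {
    expect_lt(max(abs(c0 * l_ac - (n_hbo2_ac + n_hb_ac))), 1e-10)
  })
  # mi identity holds in the truth table by construction
  w <- sim$truth$windows
  expect_equal(w$mi, w$sao2 * (1 - w$sao2) * abs(w$dtheta))
})

test_that("noiseless recovery: zero and nonzero phase delay", {
  cfg <- pipeline_config()
  est0 <- process_ppg(simulate_window(default_sim(seed = 4, dtheta = 0))$record,
                      cfg)
  expect_lt(max(abs(est0$dtheta)), 1e-6)
  expect_lt(max(est0$mi), 1e-8)

  est <- process_ppg(simulate_window(default_sim(seed = 5))$record, cfg)
  expect_lt(abs(mean(est$mi) - 0.009) / 0.009, 0.01)
  expect_equal(mean(est$sao2), 0.90, tolerance = 1e-3)
})

test_that("source drift leaves the metabolic index nearly unchanged", {
  cfg <- pipeline_config()
  clean <- simulation_params(duration_s = 300, noise_sd = 0, seed = 7)
  drift <- simulation_params(duration_s = 300, noise_sd = 0, seed = 7,
                             drift_amplitude = 0.05, drift_period_s = 120)
  m0 <- mean(process_ppg(simulate_window(clean)$record, cfg)$mi)
  m1 <- mean(process_ppg(simulate_window(drift)$record, cfg)$mi)
  expect_lt(abs(m1 - m0) / m0, 0.02)
})

test_that("seeded replicates recover phase delay and saturation closely", {
  cfg <- pipeline_config()
  for (s in 1:5) {
    p <- simulation_params(duration_s = 20, noise_sd = 0.01, seed = s)
    est <- process_ppg(simulate_window(p)$record, cfg)
    est <- est[est$quality == "ok", ]
    expect_gt(nrow(est), 0)
    expect_lt(max(abs(est$dtheta - 0.10)), 0.01)
    expect_lt(max(abs(est$sao2 - 0.90)), 0.01)
  }
})

test_that("glucose challenge profile has the stated shape", {
  g <- glucose_challenge_profile()
  tt <- seq(0, 5400, by = 10)
  v <- g(tt)
  expect_equal(v[1], 95, tolerance = 0.5)
  expect_equal(max(v), 160, tolerance = 0.5)
  expect_gt(which.max(v), which(tt == 1800))       # peak after the challenge
  expect_lt(v[length(v)], max(v))                  # decays by session end
  sess <- simulate_session(simulation_params(duration_s = 60, seed = 3),
                           ref_every_s = 20)
  expect_s3_class(sess$glucose, "glucose_series")
  expect_error(
    simulate_session(simulation_params(duration_s = 60, seed = 3),
                     glucose_profile = function(t) rep(-5, length(t))),
    "config error")
})

test_that("sensor delay is injected and recoverable", {
  sess <- simulate_session(simulation_params(duration_s = 600, seed = 8),
                           sensor_delay_s = 120, ref_every_s = 60)
  expect_equal(sess$glucose$delay_s, 120)
  g <- glucose_challenge_profile(duration_s = 600)
  # the reported value at time t is the blood value at t - delay
  expect_equal(sess$glucose$values,
               g(sess$glucose$times - 120), tolerance = 1e-9)
})
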