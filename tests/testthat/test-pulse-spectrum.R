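test_that("trough boundaries match analytic minima of a trough-started wave", {
  fs <- 100; f <- 1.25
  # minima at t = 0.1 + k/f: 5 interior troughs over 4.5 cycles
  t <- seq(0, by = 1 / fs, length.out = round(4.5 / f * fs))
  x <- -cos(2 * pi * f * (t - 0.1))
  b <- detect_pulse_boundaries(x, fs, hr_band = c(0.8, 3))
  expect_length(b, 5)
  expect_equal(t[b], 0.1 + (0:4) / f, tolerance = 1.01 / fs)
  # trimming yields exactly 4 full cycles
  win <- trim_to_boundaries(list(times = t, n_hbo2 = x, n_hb = x), b)
  expect_equal(length(win$times), 4 / f * fs + 1, tolerance = 1)
  expect_equal(win$n_beats, 4L)

  expect_error(detect_pulse_boundaries(rep(0, 1000), fs),
               "insufficient-signal")
})

test_that("boundaries stay within 20 ms of analytic troughs under 1% noise", {
  fs <- 100; f <- 1.25
  t <- seq(0, by = 1 / fs, length.out = 30 * fs)
  set.seed(42)
  x <- -cos(2 * pi * f * (t - 0.1)) + rnorm(length(t), sd = 0.01)
  filt <- design_bandpass(fs)
  b <- detect_pulse_boundaries(filtfilt(filt, x), fs)
  # judge boundaries clear of the filter settling regions at the record ends
  tb <- t[b]
  tb <- tb[tb > 1 & tb < max(t) - 1]
  troughs <- 0.1 + (0:37) / f
  nearest <- vapply(tb, function(ti) min(abs(ti - troughs)), numeric(1))
  expect_gt(length(tb), 30)
  expect_lt(max(nearest), 0.020)
})

test_that("trimming zero-means both species and is idempotent", {
  fs <- 100; f <- 1.25
  t <- seq(0, by = 1 / fs, length.out = round(4.5 / f * fs))
  sig <- list(times = t,
              n_hbo2 = -cos(2 * pi * f * (t - 0.1)) + 0.3,
              n_hb = -0.5 * cos(2 * pi * f * (t - 0.12)) - 0.1)
  b <- detect_pulse_boundaries(sig$n_hbo2 - mean(sig$n_hbo2), fs)
  win <- trim_to_boundaries(sig, b)
  expect_lt(abs(mean(win$n_hbo2)), 1e-6 * max(abs(win$n_hbo2)))
  expect_lt(abs(mean(win$n_hb)), 1e-6 * max(abs(win$n_hb)))
  win2 <- trim_to_boundaries(win, c(1, length(win$times)))
  expect_equal(win2$n_hbo2, win$n_hbo2, tolerance = 1e-12)
})

test_that("spectrum resamples to the next power of two and satisfies Parseval", {
  w <- make_sine_window(dur = 4)            # 400 samples
  w$n_hbo2 <- w$n_hbo2[1:400]; w$n_hb <- w$n_hb[1:400]
  sp <- window_spectrum(w)
  expect_equal(sp$n_fft, 512L)
  expect_equal(sp$freq[2] - sp$freq[1], 1 / 4, tolerance = 1e-12)

  w512 <- make_sine_window(dur = 5.12)
  sp512 <- window_spectrum(w512)
  expect_equal(sp512$n_fft, 512L)

  # Parseval: windowed-signal energy equals spectrum energy / N
  e_time <- sum(sp$windowed$hbo2^2)
  e_freq <- sum(Mod(sp$x_hbo2)^2) / sp$n_fft
  expect_equal(e_freq, e_time, tolerance = 1e-6)
})

test_that("main peak lands on the cardiac bin with calibrated amplitudes", {
  sp <- window_spectrum(make_sine_window(f = 1.25, dur = 4))
  pk <- main_peak(sp)
  expect_equal(pk$freq, 1.25)              # bin 5 of a 4-s span
  expect_equal(pk$bin, 6L)                 # 1-based FFT index (DC = 1)
  expect_equal(pk$a_hbo2, 0.009, tolerance = 0.01)
  expect_equal(pk$a_hb, 0.001, tolerance = 0.01)
  expect_equal(pk$quality, "ok")

  # harmonic weaker than fundamental is never selected
  w <- make_sine_window(f = 1.25, dur = 4)
  t <- w$times
  w$n_hbo2 <- w$n_hbo2 + 0.004 * sin(2 * pi * 2.5 * t)
  pk2 <- main_peak(window_spectrum(w))
  expect_equal(pk2$freq, 1.25)

  # white noise only: SNR below threshold
  set.seed(7)
  wn <- list(times = t, n_hbo2 = rnorm(400), n_hb = rnorm(400),
             sample_rate = 100)
  pk3 <- main_peak(window_spectrum(wn))
  expect_equal(pk3$quality, "low_snr")
})

test_that("amplitude fidelity under the full window chain is within 1%", {
  # noiseless on-bin pair with integer cycle count
  sp <- window_spectrum(make_sine_window(f = 1.25, dur = 4, a1 = 0.007,
                                         a2 = 0.003))
  pk <- main_peak(sp)
  expect_lt(abs(pk$a_hbo2 - 0.007) / 0.007, 0.01)
  expect_lt(abs(pk$a_hb - 0.003) / 0.003, 0.01)
})

test_that("time shifts move both phases identically (phase difference invariant)", {
  # power-of-two window length: the pure DFT shift theorem, no resampling
  fs <- 128
  t_long <- seq(0, by = 1 / fs, length.out = 4096)
  x1 <- 0.9 * sin(2 * pi * 1.25 * t_long)
  x2 <- 0.1 * sin(2 * pi * 1.25 * t_long - 0.1)
  dphase <- function(offset, n = 512, srate = fs, tl = t_long,
                     a = x1, b = x2) {
    idx <- (1 + offset):(n + offset)
    w <- list(times = tl[idx], n_hbo2 = a[idx], n_hb = b[idx],
              sample_rate = srate)
    compute_phase_delay(main_peak(window_spectrum(w)))
  }
  base <- dphase(0)
  for (k in c(7, 25, 40, 100)) {
    expect_lt(abs(dphase(k) - base), 1e-9)
  }
  # with a 400 -> 512 linear resample in the path the invariance is only
  # interpolation-limited
  fs2 <- 100
  t2 <- seq(0, by = 1 / fs2, length.out = 2000)
  y1 <- 0.9 * sin(2 * pi * 1.25 * t2)
  y2 <- 0.1 * sin(2 * pi * 1.25 * t2 - 0.1)
  base2 <- dphase(0, n = 400, srate = fs2, tl = t2, a = y1, b = y2)
  for (k in c(13, 25)) {
    expect_lt(abs(dphase(k, n = 400, srate = fs2, tl = t2, a = y1, b = y2) -
                    base2), 1e-4)
  }
})
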