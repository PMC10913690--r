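# Forward hemodynamic simulator. Builds the oxy/deoxy AC signals of the
# sinusoid model (common cardiac frequency, slowly varying amplitudes, a
# small slowly varying phase delay on the deoxy channel), derives the
# path-length pulsation from the total-hemoglobin conservation constraint,
# maps through the forward Beer-Lambert law to two-channel intensities, and
# applies source drift, additive noise and quantization. Every inverse stage
# of the pipeline is testable against the attached ground truth.

#' Simulation parameters
#'
#' The stated world of the generator. Defaults describe a resting adult
#' fingertip measurement: 75 bpm with ±5% slow heart-rate variation, 90%
#' arterial saturation, a total fundamental NIRS amplitude of 0.01 mM cm
#' (perfusion-index scale pulsation against a 1 cm baseline path and
#' 2.3 mM total hemoglobin), a 0.1 rad phase delay, a 0.3 relative second
#' harmonic, 16-bit quantization and noise at 10% of the pulsatile intensity
#' amplitude.
#'
#' @param duration_s session length in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param f_heart mean heart rate in Hz.
#' @param hr_variation relative amplitude of the slow sinusoidal heart-rate
#'   modulation.
#' @param hr_period_s period of that modulation in seconds.
#' @param c0 total hemoglobin concentration in mM (constant).
#' @param sao2 true arterial saturation fraction in (0, 1).
#' @param a_sum total fundamental NIRS amplitude `A_HbO2 + A_Hb` in mM cm
#'   (split between species by `sao2`); scalar or per-sample vector.
#' @param dtheta true phase delay in radians; scalar, per-sample vector, or
#'   a function of time.
#' @param l_lf baseline optical path length in cm; the derived path-length
#'   pulsation amplitude must stay below 5% of it.
#' @param harmonic relative amplitude of the second cardiac harmonic.
#' @param drift_amplitude relative amplitude of the multiplicative source
#'   drift applied to both channels.
#' @param drift_period_s drift period in seconds.
#' @param noise_sd additive white-noise standard deviation, relative to each
#'   channel's pulsatile (AC) intensity amplitude.
#' @param quant_bits ADC resolution in bits (0 disables quantization).
#' @param i_ref mean detected intensity in detector units.
#' @param wavelengths channel wavelengths (nm) for the forward extinction
#'   matrix.
#' @param extinction optional explicit [extinction_matrix()].
#' @param seed mandatory RNG seed.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(duration_s = 60,
                              sample_rate = 100,
                              f_heart = 1.25,
                              hr_variation = 0.05,
                              hr_period_s = 30,
                              c0 = 2.3,
                              sao2 = 0.90,
                              a_sum = 0.01,
                              dtheta = 0.10,
                              l_lf = 1.0,
                              harmonic = 0.3,
                              drift_amplitude = 0,
                              drift_period_s = 60,
                              noise_sd = 0.1,
                              quant_bits = 16,
                              i_ref = 10000,
                              wavelengths = c(650, 930),
                              extinction = NULL,
                              seed) {
  if (missing(seed) || !is.finite(seed)) stop("config error: seed is mandatory")
  if (!(sao2 > 0 && sao2 < 1)) stop("config error: sao2 must be in (0, 1)")
  p <- list(duration_s = duration_s, sample_rate = sample_rate,
            f_heart = f_heart, hr_variation = hr_variation,
            hr_period_s = hr_period_s, c0 = c0, sao2 = sao2, a_sum = a_sum,
            dtheta = dtheta, l_lf = l_lf, harmonic = harmonic,
            drift_amplitude = drift_amplitude,
            drift_period_s = drift_period_s, noise_sd = noise_sd,
            quant_bits = quant_bits, i_ref = i_ref,
            wavelengths = wavelengths, extinction = extinction,
            seed = as.integer(seed))
  dt_max <- max(abs(if (is.function(dtheta)) dtheta(seq(0, duration_s, 1))
                    else dtheta))
  if (dt_max >= pi / 4) stop("config error: |dtheta| must stay below pi/4")
  if (max(a_sum) / c0 / l_lf >= 0.05) {
    stop("config error: path-length pulsation exceeds 5% of the baseline path")
  }
  class(p) <- "simulation_params"
  p
}

as_profile <- function(x, times) {
  if (is.function(x)) x(times)
  else if (length(x) == 1) rep(x, length(times))
  else if (length(x) == length(times)) x
  else stop("config error: profile length does not match the time grid")
}

#' Simulate a dual-channel PPG record with ground truth
#'
#' Constructs the noiseless AC NIRS signals
#' `N_HbO2,AC = A_HbO2 sin(phi)` and `N_Hb,AC = A_Hb sin(phi - dtheta)`
#' (plus an optional phase-locked second harmonic), derives the path-length
#' pulsation `L_AC = (N_HbO2,AC + N_Hb,AC) / c0` enforced by total-hemoglobin
#' conservation, maps to absorbance through the forward Beer-Lambert law,
#' exponentiates to intensities and applies drift, noise and quantization.
#'
#' @param params a [simulation_params()].
#' @return list with `record` (a [ppg_record()]) and `truth` (class
#'   `simulation_truth`): the noiseless AC signals, `l_ac`, per-sample
#'   `dtheta_t`, `sao2`, instantaneous heart rate, true beat (trough) times
#'   and a per-window truth table (`windows` of `beats_per_window = 4`
#'   beats: `time_center`, `sao2`, `dtheta`, `mi`, `a_sum`).
#' @export
simulate_window <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  set.seed(p$seed)
  n <- round(p$duration_s * p$sample_rate)
  times <- seq(0, by = 1 / p$sample_rate, length.out = n)
  f_t <- p$f_heart * (1 + p$hr_variation * sin(2 * pi * times / p$hr_period_s))
  phi <- 2 * pi * cumsum(f_t) / p$sample_rate
  dtheta_t <- as_profile(p$dtheta, times)
  a_sum_t <- as_profile(p$a_sum, times)
  a1 <- a_sum_t * p$sao2
  a2 <- a_sum_t * (1 - p$sao2)
  n1 <- a1 * (sin(phi) + p$harmonic * sin(2 * phi))
  n2 <- a2 * (sin(phi - dtheta_t) + p$harmonic * sin(2 * (phi - dtheta_t)))
  l_ac <- (n1 + n2) / p$c0
  eps <- if (is.null(p$extinction)) default_extinction(p$wavelengths)
         else p$extinction
  da <- t(eps$eps %*% rbind(n1, n2))            # N x 2
  inten <- p$i_ref * 10^(-da)
  if (p$drift_amplitude > 0) {
    drift <- 1 + p$drift_amplitude * sin(2 * pi * times / p$drift_period_s)
    inten <- inten * drift
  }
  if (p$noise_sd > 0) {
    ac_amp <- apply(inten, 2, function(ch) (max(ch) - min(ch)) / 2)
    inten[, 1] <- inten[, 1] + stats::rnorm(n, 0, p$noise_sd * ac_amp[1])
    inten[, 2] <- inten[, 2] + stats::rnorm(n, 0, p$noise_sd * ac_amp[2])
  }
  if (p$quant_bits > 0) {
    lsb <- 2 * p$i_ref / 2^p$quant_bits
    inten <- round(inten / lsb) * lsb
  }
  inten[inten < 0] <- 0
  record <- ppg_record(times, inten[, 1], inten[, 2],
                       sample_rate = p$sample_rate,
                       labels = paste0(p$wavelengths, "nm"))
  # true trough times of the oxy fundamental: phi = 3*pi/2 + 2*pi*k
  k <- seq(ceiling((phi[1] - 3 * pi / 2) / (2 * pi)),
           floor((phi[n] - 3 * pi / 2) / (2 * pi)))
  beat_times <- stats::approx(phi, times, xout = 3 * pi / 2 + 2 * pi * k)$y
  beat_times <- beat_times[is.finite(beat_times)]
  truth <- structure(list(
    times = times, n_hbo2_ac = n1, n_hb_ac = n2, l_ac = l_ac,
    dtheta_t = dtheta_t, sao2 = p$sao2, f_t = f_t, a_sum_t = a_sum_t,
    beat_times = beat_times, c0 = p$c0, l_lf = p$l_lf,
    windows = window_truth(times, beat_times, p$sao2, dtheta_t, a_sum_t)
  ), class = "simulation_truth")
  list(record = record, truth = truth)
}

window_truth <- function(times, beat_times, sao2, dtheta_t, a_sum_t,
                         beats_per_window = 4) {
  nb <- length(beat_times) - 1
  starts <- seq(1, by = beats_per_window, length.out = nb %/% beats_per_window)
  rows <- lapply(starts, function(s) {
    t0 <- beat_times[s]; t1 <- beat_times[s + beats_per_window]
    sel <- times >= t0 & times <= t1
    dth <- mean(dtheta_t[sel])
    data.frame(time_center = (t0 + t1) / 2, sao2 = sao2, dtheta = dth,
               mi = sao2 * (1 - sao2) * abs(dth), a_sum = mean(a_sum_t[sel]))
  })
  do.call(rbind, rows)
}

#' Oral-challenge glucose profile
#'
#' A double-sigmoid 90-minute-style profile: fasting baseline, a rise after
#' the oral challenge, and a slower decay, normalized so the peak excursion
#' equals `peak_delta`.
#'
#' @param duration_s session length (s).
#' @param baseline fasting glucose (mg/dL).
#' @param peak_delta peak excursion above baseline (mg/dL).
#' @param t_challenge time of the oral challenge (s).
#' @param rise_tau,fall_tau sigmoid time constants (s).
#' @param rise_delay_s,fall_delay_s centers of the rise and fall sigmoids
#'   relative to the challenge (s).
#' @return a function of time (s) returning glucose in mg/dL.
#' @export
glucose_challenge_profile <- function(duration_s = 5400, baseline = 95,
                                      peak_delta = 65, t_challenge = 1800,
                                      rise_tau = 420, fall_tau = 900,
                                      rise_delay_s = 600,
                                      fall_delay_s = 2400) {
  shape <- function(t) {
    stats::plogis((t - t_challenge - rise_delay_s) / rise_tau) *
      stats::plogis(-(t - t_challenge - fall_delay_s) / fall_tau)
  }
  peak <- max(shape(seq(0, duration_s, by = 10)))
  function(t) baseline + peak_delta * shape(t) / peak
}

#' Simulate a full oral-challenge session with a paired reference
#'
#' Drives the phase delay from a blood-glucose profile through a linear
#' coupling (default 0.1 rad per 40 mg/dL, the observed scale) on top of a
#' fasting baseline delay, optionally modulates perfusion (the path-length
#' LF component, and with it the pulsatile amplitude as `L_LF^n_true`), and
#' emits the PPG record, a reference glucose series sampled every
#' `ref_every_s` seconds with a constant sensor delay, and the ground truth.
#'
#' @param params a [simulation_params()] (its `duration_s` rules).
#' @param glucose_profile function of time (s) giving blood glucose in
#'   mg/dL; default [glucose_challenge_profile()] matched to `duration_s`.
#' @param coupling list with `gain` (rad per mg/dL), `dtheta0` (fasting
#'   phase delay, rad) and `g0` (fasting glucose, mg/dL).
#' @param sensor_delay_s constant reference sensor delay (s).
#' @param ref_every_s reference sampling interval (s).
#' @param perfusion list with `amplitude` (relative slow modulation of the
#'   LF path length), `period_s`, `phase` and `n_true` (exponent coupling
#'   the pulsatile amplitude to the LF path).
#' @return list with `record`, `glucose` (a [glucose_series()] carrying
#'   `delay_s = sensor_delay_s`), and `truth`.
#' @export
simulate_session <- function(params,
                             glucose_profile = NULL,
                             coupling = list(gain = 0.1 / 40, dtheta0 = 0.10,
                                             g0 = 95),
                             sensor_delay_s = 0,
                             ref_every_s = 300,
                             perfusion = list(amplitude = 0, period_s = 1300,
                                              phase = pi / 3, n_true = 0.5)) {
  stopifnot(inherits(params, "simulation_params"))
  if (is.null(glucose_profile)) {
    glucose_profile <- glucose_challenge_profile(duration_s = params$duration_s)
  }
  n <- round(params$duration_s * params$sample_rate)
  times <- seq(0, by = 1 / params$sample_rate, length.out = n)
  g_t <- glucose_profile(times)
  if (any(g_t <= 0)) stop("config error: glucose profile must be positive")
  llf_rel <- 1 + perfusion$amplitude *
    sin(2 * pi * times / perfusion$period_s + perfusion$phase)
  dtheta_t <- (coupling$dtheta0 + coupling$gain * (g_t - coupling$g0)) *
    llf_rel^(1 - perfusion$n_true)
  a_sum_t <- as_profile(params$a_sum, times) * llf_rel^perfusion$n_true
  p <- params
  p$dtheta <- dtheta_t
  p$a_sum <- a_sum_t
  sim <- simulate_window(p)
  ref_times <- seq(0, params$duration_s, by = ref_every_s)
  ref_times <- ref_times[ref_times > 0]
  if (length(ref_times) == 0) {
    stop("config error: ref_every_s exceeds the session duration")
  }
  glucose <- glucose_series(ref_times,
                            glucose_profile(ref_times - sensor_delay_s),
                            delay_s = sensor_delay_s)
  sim$truth$glucose_t <- g_t
  sim$truth$llf_rel <- llf_rel
  list(record = sim$record, glucose = glucose, truth = sim$truth)
}

#' Sweep the alpha-correction exponent and trace r(n)
#'
#' Re-evaluates the corrected index MI' for each exponent in `n_grid`,
#' re-runs the trend post-processing, and reports the Pearson correlation
#' against the reference at each n. `r(1)` equals the uncorrected
#' correlation exactly since alpha is identically 1 there.
#'
#' @param estimates window-estimate data frame from [process_ppg()].
#' @param glucose a [glucose_series()].
#' @param n_grid exponents to evaluate, each in (0, 1].
#' @param config the [pipeline_config()] used for post-processing.
#' @return data frame with columns `n` and `r`.
#' @export
sweep_alpha_exponent <- function(estimates, glucose, n_grid = seq(0.1, 1, 0.1),
                                 config = pipeline_config()) {
  a0 <- attr(estimates, "a0_sum")
  if (is.null(a0)) stop("format error: estimates lack an a0_sum attribute")
  ref <- compensate_delay(glucose)
  r_of_n <- vapply(n_grid, function(n) {
    bl <- alpha_baseline(a0, n = n, provenance = "config")
    al <- alpha_correction(estimates$a_hbo2, estimates$a_hb, bl)
    mi_c <- corrected_index(estimates$mi, al)
    ser <- chunk_and_average(estimates$time_center, mi_c, estimates$quality,
                             chunk_s = config$chunk_s, k = config$outlier_k,
                             max_frac = config$outlier_max_frac)
    ser <- smooth_mi_series(ser, order = config$savgol_order,
                            window = config$savgol_window,
                            max_gap_chunks = config$max_gap_chunks)
    v <- interpolate_to(ser$time_s, ser$smoothed, ref$times)
    ok <- is.finite(v)
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(v[ok], ref$values[ok])
  }, numeric(1))
  data.frame(n = n_grid, r = r_of_n)
}
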