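# Per-window estimates: arterial saturation, phase delay, metabolic index
# and the perfusion (alpha) correction.

#' Wrap an angle to (-pi, pi]
#'
#' @param x angle(s) in radians.
#' @return wrapped angle(s).
#' @export
wrap_phase <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Arterial oxygen saturation from fundamental amplitudes
#'
#' `SaO2 = A_HbO2 / (A_HbO2 + A_Hb)` — the ratio of the oxyhemoglobin
#' cardiac-fundamental amplitude to the total.
#'
#' @param a_hbo2,a_hb nonnegative fundamental amplitudes (mM cm).
#' @return saturation fraction in \[0, 1\].
#' @export
compute_sao2 <- function(a_hbo2, a_hb) {
  if (any(a_hbo2 < 0) || any(a_hb < 0)) {
    stop("domain error: amplitudes must be nonnegative")
  }
  s <- a_hbo2 + a_hb
  if (any(s <= 0)) stop("domain error: zero amplitude sum")
  a_hbo2 / s
}

#' Phase delay of deoxy- behind oxyhemoglobin
#'
#' `dtheta = phase(HbO2) - phase(Hb)` at the cardiac fundamental, wrapped to
#' (-pi, pi]. Positive when the deoxyhemoglobin signal lags the
#' oxyhemoglobin signal (the physiologically observed orientation).
#'
#' @param peak a `spectral_peak` from [main_peak()], or a list with
#'   `phase_hbo2` and `phase_hb`.
#' @return phase delay in radians.
#' @export
compute_phase_delay <- function(peak) {
  wrap_phase(peak$phase_hbo2 - peak$phase_hb)
}

#' Metabolic index
#'
#' `MI = SaO2 * (1 - SaO2) * |dtheta|`: the dimensionless index proportional
#' to the per-beat deoxyhemoglobin concentration pulsation, up to the
#' subject's total hemoglobin and perfusion factors. Zero at full or zero
#' saturation and at zero phase delay.
#'
#' @param sao2 saturation fraction in \[0, 1\].
#' @param dtheta phase delay in radians (sign is ignored).
#' @return nonnegative MI.
#' @export
metabolic_index <- function(sao2, dtheta) {
  if (any(sao2 < 0 | sao2 > 1)) stop("domain error: sao2 outside [0, 1]")
  sao2 * (1 - sao2) * abs(dtheta)
}

#' Alpha-correction baseline
#'
#' The normalization constant `A_HbO2,0 + A_Hb,0` of the perfusion
#' correction, with the exponent `n` it will be used with.
#'
#' @param a0_sum positive baseline amplitude sum (mM cm).
#' @param n power exponent in (0, 1].
#' @param provenance `"config"` or `"baseline-interval"`.
#' @return object of class `alpha_baseline`.
#' @export
alpha_baseline <- function(a0_sum, n = 0.5,
                           provenance = c("config", "baseline-interval")) {
  provenance <- match.arg(provenance)
  if (!is.finite(a0_sum) || a0_sum <= 0) {
    stop("domain error: baseline amplitude sum must be positive")
  }
  if (!(n > 0 && n <= 1)) stop("config error: n must be in (0, 1]")
  structure(list(a0_sum = a0_sum, n = n, provenance = provenance),
            class = "alpha_baseline")
}

#' Perfusion correction coefficient alpha
#'
#' `alpha = ((A_HbO2 + A_Hb) / a0_sum)^(1 - 1/n)`. With `n = 1` the exponent
#' is zero and alpha is identically 1 (no correction). Because `1 - 1/n <= 0`,
#' alpha grows as the pulsatile amplitude falls — the false-hyperglycemia
#' hazard that motivates the amplitude floor applied upstream.
#'
#' @param a_hbo2,a_hb fundamental amplitudes (mM cm).
#' @param baseline an [alpha_baseline()].
#' @return alpha > 0 (NA where the amplitude sum is nonpositive).
#' @export
alpha_correction <- function(a_hbo2, a_hb, baseline) {
  stopifnot(inherits(baseline, "alpha_baseline"))
  s <- a_hbo2 + a_hb
  out <- rep(NA_real_, length(s))
  pos <- is.finite(s) & s > 0
  out[pos] <- (s[pos] / baseline$a0_sum)^(1 - 1 / baseline$n)
  out
}

#' Amplitude-corrected metabolic index
#'
#' `MI' = alpha * MI`.
#'
#' @param mi nonnegative metabolic index.
#' @param alpha positive correction coefficient.
#' @return corrected index.
#' @export
corrected_index <- function(mi, alpha) {
  if (any(mi < 0, na.rm = TRUE)) stop("domain error: mi must be >= 0")
  mi * alpha
}

#' Deoxyhemoglobin pulsation amplitude (validation oracle)
#'
#' Evaluates the oscillation amplitude of the deoxyhemoglobin concentration
#' pulsation implied by the sinusoid model, either by the small-angle
#' closed form `(A_HbO2 + A_Hb)/L * SaO2 (1 - SaO2) |dtheta|` or by the
#' exact two-sinusoid difference amplitude
#' `2 |sin(dtheta/2)| / L * A_HbO2 A_Hb / (A_HbO2 + A_Hb)`. Used to validate
#' the simulator and the small-angle approximation, not by the pipeline.
#'
#' @param a_hbo2,a_hb fundamental amplitudes (mM cm).
#' @param L optical path length (cm), > 0.
#' @param dtheta phase delay (rad).
#' @param method `"small_angle"` (default) or `"exact"`.
#' @return pulsation amplitude in mM.
#' @export
chb_ac_amplitude <- function(a_hbo2, a_hb, L, dtheta,
                             method = c("small_angle", "exact")) {
  method <- match.arg(method)
  if (any(L <= 0)) stop("domain error: path length must be positive")
  s <- a_hbo2 + a_hb
  sao2 <- ifelse(s > 0, a_hbo2 / s, NA_real_)
  if (method == "small_angle") {
    s / L * sao2 * (1 - sao2) * abs(dtheta)
  } else {
    2 * abs(sin(dtheta / 2)) / L * ifelse(s > 0, a_hbo2 * a_hb / s, 0)
  }
}

#' Ideal measurement-time bounds
#'
#' Total recording time needed for a stable instantaneous MI estimate under
#' ideal conditions: `windows * beats_per_window` heartbeats at the extremes
#' of the resting adult heart-rate range. With 3 to 5 windows of about 4
#' beats and 60-100 bpm this spans 7.2 to 20 seconds.
#'
#' @param windows_range number of windows (min, max).
#' @param beats_per_window beats per window.
#' @param hr_bpm heart-rate range in beats per minute (min, max).
#' @return named numeric `c(min_s, max_s)`.
#' @export
measurement_time_bounds <- function(windows_range = c(3, 5),
                                    beats_per_window = 4,
                                    hr_bpm = c(60, 100)) {
  c(min_s = windows_range[1] * beats_per_window * 60 / hr_bpm[2],
    max_s = windows_range[2] * beats_per_window * 60 / hr_bpm[1])
}
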