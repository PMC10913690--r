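# Front half of the per-window analysis: pulse-boundary trimming, resampling
# to a power of two, Hamming windowing, FFT, and cardiac-fundamental
# amplitude/phase extraction for both hemoglobin species.

#' Detect pulse (trough) boundaries in a band-passed AC signal
#'
#' Successive waveform troughs — local minima below zero separated by at
#' least one minimum cardiac period `1/hr_band[2]` — mark the beginnings and
#' ends of pulse waves. The oxyhemoglobin channel is used as the timing
#' master for both species so the inter-channel phase relationship is kept
#' intact.
#'
#' @param ac_signal band-passed (zero-mean) signal.
#' @param sample_rate sampling rate in Hz.
#' @param hr_band heart-rate search band in Hz.
#' @return integer vector of boundary sample indices (>= 3 beats, i.e. >= 4
#'   boundaries are not required; >= 3 boundaries are).
#' @export
detect_pulse_boundaries <- function(ac_signal, sample_rate, hr_band = c(0.8, 3)) {
  n <- length(ac_signal)
  if (n < 3) stop("insufficient-signal error: too few samples")
  x <- ac_signal
  interior <- 2:(n - 1)
  is_min <- x[interior] < x[interior - 1] & x[interior] <= x[interior + 1] &
    x[interior] < 0
  cand <- interior[is_min]
  if (length(cand) == 0) {
    stop("insufficient-signal error: no pulse troughs detected")
  }
  min_sep <- ceiling(sample_rate / hr_band[2])
  # greedy pass keeping the deeper trough when two candidates are too close
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0 || i - keep[length(keep)] >= min_sep) {
      keep <- c(keep, i)
    } else if (x[i] < x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  if (length(keep) < 4) {  # fewer than 3 full beats
    stop("insufficient-signal error: fewer than 3 beats detected")
  }
  keep
}

#' Trim both species to common pulse boundaries
#'
#' Cuts both AC series to the span `[first boundary, last boundary]` so the
#' window holds an integer number of pulse waves, then subtracts the
#' per-species mean over the trimmed span (the cycle-average-zero
#' assumption).
#'
#' @param signals list with `n_hbo2`, `n_hb` (band-passed AC series) and
#'   `times`.
#' @param boundaries sample indices from [detect_pulse_boundaries()]; only
#'   the first and last are used.
#' @return list of class `analysis_window`: `times`, `n_hbo2`, `n_hb`,
#'   `boundaries` (re-indexed), `n_beats`, `sample_rate`.
#' @export
trim_to_boundaries <- function(signals, boundaries) {
  if (length(boundaries) < 2) stop("insufficient-signal error: need >= 2 boundaries")
  b0 <- boundaries[1]; b1 <- boundaries[length(boundaries)]
  idx <- b0:b1
  times <- signals$times[idx]
  sr <- 1 / stats::median(diff(times))
  structure(list(
    times = times,
    n_hbo2 = signals$n_hbo2[idx] - mean(signals$n_hbo2[idx]),
    n_hb = signals$n_hb[idx] - mean(signals$n_hb[idx]),
    boundaries = as.integer(boundaries - b0 + 1L),
    n_beats = length(boundaries) - 1L,
    sample_rate = sr
  ), class = "analysis_window")
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Windowed spectrum of an analysis window
#'
#' Each species is resampled by linear interpolation to the smallest power
#' of two at or above the original length, over the same time span (so an
#' integer number of pulse waves stays on-bin), a Hamming window is applied,
#' and the DFT is returned with its frequency grid. Frequency resolution is
#' the reciprocal of the window time span.
#'
#' @param window an `analysis_window` from [trim_to_boundaries()], or any
#'   list with `n_hbo2`, `n_hb`, `sample_rate`.
#' @return list of class `window_spectrum`: `freq`, complex `x_hbo2`,
#'   `x_hb`, `n_fft`, `window_sum` (sum of the Hamming window, for amplitude
#'   calibration).
#' @export
window_spectrum <- function(window) {
  n <- length(window$n_hbo2)
  span <- n / window$sample_rate
  p <- next_pow2(n)
  if (p != n) {
    t_old <- seq(0, by = 1 / window$sample_rate, length.out = n)
    t_new <- seq(0, by = span / p, length.out = p)
    y1 <- stats::approx(t_old, window$n_hbo2, xout = t_new, rule = 2)$y
    y2 <- stats::approx(t_old, window$n_hb, xout = t_new, rule = 2)$y
  } else {
    y1 <- window$n_hbo2
    y2 <- window$n_hb
  }
  # periodic (DFT-even) Hamming: an on-bin tone then leaks into adjacent
  # bins only, so on-bin amplitude/phase extraction is exact
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, p - 1) / p)
  structure(list(
    freq = seq(0, p - 1) / span,
    x_hbo2 = stats::fft(y1 * w),
    x_hb = stats::fft(y2 * w),
    n_fft = p,
    window_sum = sum(w),
    windowed = list(hbo2 = y1 * w, hb = y2 * w)
  ), class = "window_spectrum")
}

#' Locate the cardiac fundamental and extract amplitudes and phases
#'
#' The main peak is the bin of maximum oxyhemoglobin magnitude inside the
#' heart-rate band; both species are evaluated at that same bin. Fundamental
#' amplitudes are calibrated as `2 |X[k]| / sum(w)` (exact for an on-bin
#' sinusoid under any window `w`). Spectral SNR is the peak magnitude over
#' the median off-peak magnitude (DC and the peak's immediate neighbours
#' excluded).
#'
#' @param spectra a `window_spectrum`.
#' @param hr_band heart-rate band in Hz.
#' @param snr_min minimum SNR for quality `"ok"`.
#' @return list of class `spectral_peak`: `freq`, `bin` (1-based index),
#'   `a_hbo2`, `a_hb`, `phase_hbo2`, `phase_hb`, `snr`, `quality`.
#' @export
main_peak <- function(spectra, hr_band = c(0.8, 3), snr_min = 10) {
  half <- 2:(spectra$n_fft %/% 2 + 1)  # positive frequencies, DC excluded
  freq <- spectra$freq[half]
  if (hr_band[2] >= max(freq)) stop("config error: hr_band outside spectrum")
  in_band <- which(freq >= hr_band[1] & freq <= hr_band[2])
  if (length(in_band) == 0) stop("config error: empty hr_band on this grid")
  mag1 <- Mod(spectra$x_hbo2[half])
  k <- in_band[which.max(mag1[in_band])]
  # noise floor from in-band bins only (the band-pass upstream suppresses
  # everything else), excluding the peak and its second harmonic
  floor_band <- which(freq >= hr_band[1] & freq <= min(4 * hr_band[2], max(freq)))
  off <- setdiff(floor_band, c((k - 1):(k + 1), (2 * k - 1):(2 * k + 1)))
  if (length(off) < 5) off <- setdiff(seq_along(freq), (k - 1):(k + 1))
  noise_floor <- stats::median(mag1[off])
  snr <- if (noise_floor > 0) mag1[k] / noise_floor else Inf
  cal <- 2 / spectra$window_sum
  pk <- list(
    freq = freq[k],
    bin = k + 1L,  # index into the full FFT vector
    a_hbo2 = cal * mag1[k],
    a_hb = cal * Mod(spectra$x_hb[half][k]),
    phase_hbo2 = Arg(spectra$x_hbo2[half][k]),
    phase_hb = Arg(spectra$x_hb[half][k]),
    snr = snr,
    quality = if (snr >= snr_min) "ok" else "low_snr"
  )
  class(pk) <- "spectral_peak"
  pk
}

#' @export
print.spectral_peak <- function(x, ...) {
  cat(sprintf(
    "<spectral_peak> %.3f Hz, A_HbO2 %.4g, A_Hb %.4g, SNR %.1f [%s]\n",
    x$freq, x$a_hbo2, x$a_hb, x$snr, x$quality))
  invisible(x)
}
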