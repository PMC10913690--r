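#' Pipeline configuration
#'
#' Collects every tunable parameter of the MI pipeline in one validated
#' object. Defaults follow the reference processing chain: a Butterworth
#' band-pass designed from a 0.8--10 Hz passband (3 dB maximum loss) and a
#' 10 dB minimum stopband attenuation, four-beat analysis windows, one-minute
#' chunking, and a Savitzky-Golay smoother of order 1 and window 29.
#'
#' @param wavelengths length-2 numeric, channel wavelengths in nm. The pair
#'   650/930 nm has embedded extinction coefficients; any other pair needs an
#'   explicit `extinction` matrix.
#' @param extinction optional 2x2 extinction matrix (see
#'   [extinction_matrix()]); `NULL` selects the embedded table for
#'   `wavelengths`.
#' @param bpf_pass passband edges in Hz.
#' @param bpf_stop stopband edges in Hz (the reference chain leaves these
#'   open; defaults 0.4 and 15 Hz).
#' @param bpf_rp maximum passband loss in dB (single pass).
#' @param bpf_rs minimum stopband attenuation in dB (single pass).
#' @param hr_band heart-rate search band in Hz in which the cardiac
#'   fundamental is located.
#' @param beats_per_window number of heartbeats per analysis window.
#' @param chunk_s chunk length in seconds for trend averaging.
#' @param outlier_k multiplier of the IQR outlier fence within a chunk.
#' @param outlier_max_frac maximum fraction of a chunk that may be rejected
#'   as outliers before the whole chunk is marked missing.
#' @param max_gap_chunks longest run of missing chunks bridged by
#'   interpolation before smoothing; longer gaps stay missing.
#' @param savgol_order,savgol_window Savitzky-Golay polynomial order and
#'   (odd) window length, in chunks.
#' @param alpha_n power exponent n in (0, 1] of the perfusion (alpha)
#'   correction; `n = 1` disables the correction.
#' @param baseline_interval_s length-2 numeric, session interval (seconds)
#'   whose median amplitude sum defines the alpha-correction baseline.
#' @param a0_sum optional explicit alpha baseline amplitude sum (mM cm);
#'   overrides `baseline_interval_s`.
#' @param polarity `"intensity"` if the channels are transmitted intensity
#'   (decreasing at systole), `"inverted"` if the ADC inverts them.
#' @param log_base 10 or `exp(1)`; logarithm convention of the absorbance and
#'   the extinction table.
#' @param snr_min minimum spectral SNR (peak magnitude over median off-peak
#'   in-band magnitude) for a window to be quality `"ok"`. The default 10
#'   was calibrated on the simulator: pure-noise windows stay below ~7 while
#'   signal windows at three times the default noise stay above ~20.
#' @param amp_floor minimum fundamental amplitude sum (mM cm); windows below
#'   it are rejected to guard against false hyperglycemia from poor
#'   perfusion.
#' @param glucose_delay_s constant reference-sensor delay in seconds.
#'
#' @return an object of class `pipeline_config` (a named list).
#' @seealso [read_pipeline_config()] to load one from a flat YAML file.
#' @export
pipeline_config <- function(wavelengths = c(650, 930),
                            extinction = NULL,
                            bpf_pass = c(0.8, 10),
                            bpf_stop = c(0.4, 15),
                            bpf_rp = 3,
                            bpf_rs = 10,
                            hr_band = c(0.8, 3),
                            beats_per_window = 4,
                            chunk_s = 60,
                            outlier_k = 1.5,
                            outlier_max_frac = 0.4,
                            max_gap_chunks = 3,
                            savgol_order = 1,
                            savgol_window = 29,
                            alpha_n = 0.5,
                            baseline_interval_s = c(0, 600),
                            a0_sum = NULL,
                            polarity = c("intensity", "inverted"),
                            log_base = 10,
                            snr_min = 10,
                            amp_floor = 1e-5,
                            glucose_delay_s = 0) {
  polarity <- match.arg(polarity)
  cfg <- list(
    wavelengths = as.numeric(wavelengths),
    extinction = extinction,
    bpf_pass = as.numeric(bpf_pass), bpf_stop = as.numeric(bpf_stop),
    bpf_rp = as.numeric(bpf_rp), bpf_rs = as.numeric(bpf_rs),
    hr_band = as.numeric(hr_band),
    beats_per_window = as.integer(beats_per_window),
    chunk_s = as.numeric(chunk_s),
    outlier_k = as.numeric(outlier_k),
    outlier_max_frac = as.numeric(outlier_max_frac),
    max_gap_chunks = as.integer(max_gap_chunks),
    savgol_order = as.integer(savgol_order),
    savgol_window = as.integer(savgol_window),
    alpha_n = as.numeric(alpha_n),
    baseline_interval_s = as.numeric(baseline_interval_s),
    a0_sum = if (is.null(a0_sum)) NULL else as.numeric(a0_sum),
    polarity = polarity,
    log_base = as.numeric(log_base),
    snr_min = as.numeric(snr_min),
    amp_floor = as.numeric(amp_floor),
    glucose_delay_s = as.numeric(glucose_delay_s)
  )
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$wavelengths) == 2)
  if (!(cfg$alpha_n > 0 && cfg$alpha_n <= 1)) {
    stop("config error: alpha exponent n must be in (0, 1], got ", cfg$alpha_n)
  }
  if (cfg$savgol_window %% 2L == 0L || cfg$savgol_window <= cfg$savgol_order) {
    stop("config error: savgol_window must be odd and greater than savgol_order")
  }
  if (length(cfg$bpf_pass) != 2 || diff(cfg$bpf_pass) <= 0) {
    stop("config error: bpf_pass must be increasing band edges")
  }
  if (!(cfg$bpf_stop[1] < cfg$bpf_pass[1] && cfg$bpf_stop[2] > cfg$bpf_pass[2])) {
    stop("config error: stopband edges must bracket the passband")
  }
  if (length(cfg$hr_band) != 2 || diff(cfg$hr_band) <= 0 || cfg$hr_band[1] <= 0) {
    stop("config error: hr_band must be positive increasing band edges")
  }
  if (cfg$beats_per_window < 2) stop("config error: beats_per_window < 2")
  if (!cfg$log_base %in% c(10, exp(1))) {
    stop("config error: log_base must be 10 or exp(1)")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Every field of [pipeline_config()] is exposed under its own name; unknown
#' keys are an error so typos do not silently fall back to defaults. The
#' `extinction` key, if present, is a row-major length-4 numeric vector
#' (eps\[channel, species\] with species order HbO2, Hb).
#'
#' @param path path to the YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config error: expected a key-value mapping in ", path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(raw$extinction)) {
    ex <- as.numeric(unlist(raw$extinction))
    if (length(ex) != 4) stop("config error: extinction must have 4 values")
    raw$extinction <- extinction_matrix(
      matrix(ex, 2, 2, byrow = TRUE),
      wavelengths = if (is.null(raw$wavelengths)) c(650, 930)
                    else as.numeric(unlist(raw$wavelengths)),
      log_base = if (is.null(raw$log_base)) 10 else as.numeric(raw$log_base)
    )
  }
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to a flat YAML file
#'
#' @param config a `pipeline_config`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  if (!is.null(out$extinction)) {
    out$extinction <- as.numeric(t(out$extinction$eps))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  wavelengths     : %s nm\n", paste(x$wavelengths, collapse = "/")))
  cat(sprintf("  band-pass       : %g-%g Hz pass (%g dB), %g-%g Hz stop (%g dB)\n",
              x$bpf_pass[1], x$bpf_pass[2], x$bpf_rp,
              x$bpf_stop[1], x$bpf_stop[2], x$bpf_rs))
  cat(sprintf("  hr band         : %g-%g Hz; %d beats/window\n",
              x$hr_band[1], x$hr_band[2], x$beats_per_window))
  cat(sprintf("  trend           : %g s chunks, SG order %d window %d\n",
              x$chunk_s, x$savgol_order, x$savgol_window))
  cat(sprintf("  alpha           : n = %g, baseline %g-%g s\n",
              x$alpha_n, x$baseline_interval_s[1], x$baseline_interval_s[2]))
  cat(sprintf("  quality         : SNR >= %g, amplitude sum >= %g\n",
              x$snr_min, x$amp_floor))
  invisible(x)
}
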