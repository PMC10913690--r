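# End-to-end orchestration: intensities -> NIRS -> band-pass -> windowed
# spectral estimates -> MI/MI' -> per-minute trend, plus the run manifest.

#' Process a PPG record into per-window MI estimates
#'
#' Runs the full inverse chain: Beer-Lambert inversion with the configured
#' extinction matrix, zero-phase Butterworth band-pass, pulse-boundary
#' detection on the oxyhemoglobin channel, non-overlapping windows of
#' `beats_per_window` beats, per-window FFT with Hamming windowing, and the
#' SaO2 / phase-delay / MI / alpha / MI' estimates. Windows failing the SNR
#' gate or the amplitude floor are flagged, not dropped.
#'
#' @param record a [ppg_record()].
#' @param config a [pipeline_config()].
#' @return data frame of class `window_estimates` with columns
#'   `time_center`, `a_hbo2`, `a_hb`, `sao2`, `dtheta`, `mi`, `alpha`,
#'   `mi_corrected`, `snr`, `freq`, `quality`; attributes `a0_sum`,
#'   `filter_order`, `config`.
#' @export
process_ppg <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "ppg_record"))
  eps <- if (is.null(config$extinction)) default_extinction(config$wavelengths)
         else config$extinction
  da <- absorbance_change(record, log_base = config$log_base)
  nirs <- invert_mbll(da, eps)
  filt <- design_bandpass(record$sample_rate, config$bpf_pass,
                          config$bpf_stop, config$bpf_rp, config$bpf_rs)
  ac <- list(times = nirs$times,
             n_hbo2 = filtfilt(filt, nirs$n_hbo2),
             n_hb = filtfilt(filt, nirs$n_hb))
  boundaries <- detect_pulse_boundaries(ac$n_hbo2, record$sample_rate,
                                        config$hr_band)
  bpw <- config$beats_per_window
  n_windows <- (length(boundaries) - 1) %/% bpw
  if (n_windows < 1) {
    stop("insufficient-signal error: not enough beats for one analysis window")
  }
  rows <- vector("list", n_windows)
  for (wi in seq_len(n_windows)) {
    bs <- boundaries[((wi - 1) * bpw + 1):((wi * bpw) + 1)]
    win <- trim_to_boundaries(ac, bs)
    spec <- window_spectrum(win)
    pk <- main_peak(spec, config$hr_band, config$snr_min)
    sao2 <- compute_sao2(pk$a_hbo2, pk$a_hb)
    dth <- compute_phase_delay(pk)
    quality <- pk$quality
    if (pk$a_hbo2 + pk$a_hb < config$amp_floor) quality <- "rejected"
    rows[[wi]] <- data.frame(
      time_center = mean(range(win$times)),
      a_hbo2 = pk$a_hbo2, a_hb = pk$a_hb,
      sao2 = sao2, dtheta = dth,
      mi = metabolic_index(sao2, dth),
      snr = pk$snr, freq = pk$freq,
      quality = quality, stringsAsFactors = FALSE
    )
  }
  est <- do.call(rbind, rows)
  a0 <- config$a0_sum
  prov <- "config"
  if (is.null(a0)) {
    in_bl <- est$time_center >= config$baseline_interval_s[1] &
      est$time_center <= config$baseline_interval_s[2] & est$quality == "ok"
    if (!any(in_bl)) in_bl <- est$quality == "ok"
    if (!any(in_bl)) in_bl <- rep(TRUE, nrow(est))
    a0 <- stats::median(est$a_hbo2[in_bl] + est$a_hb[in_bl])
    prov <- "baseline-interval"
  }
  bl <- alpha_baseline(a0, n = config$alpha_n, provenance = prov)
  est$alpha <- alpha_correction(est$a_hbo2, est$a_hb, bl)
  est$mi_corrected <- corrected_index(est$mi, est$alpha)
  est <- est[, c("time_center", "a_hbo2", "a_hb", "sao2", "dtheta", "mi",
                 "alpha", "mi_corrected", "snr", "freq", "quality")]
  attr(est, "a0_sum") <- a0
  attr(est, "filter_order") <- filt$order
  attr(est, "config") <- config
  class(est) <- c("window_estimates", "data.frame")
  est
}

#' Post-process window estimates into a per-minute trend
#'
#' Chunks MI and MI' into `chunk_s` chunks with IQR outlier rejection,
#' bridges short gaps, and smooths with the configured Savitzky-Golay
#' filter.
#'
#' @param estimates output of [process_ppg()].
#' @param config a [pipeline_config()].
#' @return data frame with `time_s`, `mi_raw`, `mi`, `mi_corrected_raw`,
#'   `mi_corrected`, `n`, `n_rejected`.
#' @export
postprocess_mi <- function(estimates, config = pipeline_config()) {
  ser <- chunk_and_average(estimates$time_center, estimates$mi,
                           estimates$quality, chunk_s = config$chunk_s,
                           k = config$outlier_k,
                           max_frac = config$outlier_max_frac)
  ser <- smooth_mi_series(ser, order = config$savgol_order,
                          window = config$savgol_window,
                          max_gap_chunks = config$max_gap_chunks)
  serc <- chunk_and_average(estimates$time_center, estimates$mi_corrected,
                            estimates$quality, chunk_s = config$chunk_s,
                            k = config$outlier_k,
                            max_frac = config$outlier_max_frac)
  serc <- smooth_mi_series(serc, order = config$savgol_order,
                           window = config$savgol_window,
                           max_gap_chunks = config$max_gap_chunks)
  data.frame(time_s = ser$time_s, mi_raw = ser$raw, mi = ser$smoothed,
             mi_corrected_raw = serc$raw, mi_corrected = serc$smoothed,
             n = ser$n, n_rejected = ser$n_rejected)
}

#' Run the full pipeline on a record
#'
#' [process_ppg()] followed by [postprocess_mi()], bundled with a run
#' manifest.
#'
#' @param record a [ppg_record()].
#' @param config a [pipeline_config()].
#' @param inputs optional named character vector of input file paths whose
#'   digests enter the manifest.
#' @return list with `estimates`, `trend`, `manifest`.
#' @export
process_session <- function(record, config = pipeline_config(),
                            inputs = character(0)) {
  est <- process_ppg(record, config)
  trend <- if (any(est$quality == "ok")) {
    postprocess_mi(est, config)
  } else {
    warning("all analysis windows were flagged low quality; no trend computed")
    NULL
  }
  manifest <- run_manifest(config, inputs = inputs, estimates = est)
  list(estimates = est, trend = trend, manifest = manifest)
}

#' Build a reproducible run manifest
#'
#' Snapshot of the configuration (including every defaulted value), package
#' version, input digests and window counts, so any run can be audited and
#' reproduced.
#'
#' @param config a [pipeline_config()].
#' @param inputs named character vector of input file paths.
#' @param estimates optional window estimates for the counts.
#' @param seed optional RNG seed used by the run.
#' @return named list of class `run_manifest`.
#' @export
run_manifest <- function(config, inputs = character(0), estimates = NULL,
                         seed = NULL) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  m <- list(
    package_version = as.character(utils::packageVersion("hemophase")),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    seed = seed,
    input_digests = digests,
    windows_total = if (is.null(estimates)) NA_integer_ else nrow(estimates),
    windows_ok = if (is.null(estimates)) NA_integer_
                 else sum(estimates$quality == "ok"),
    windows_flagged = if (is.null(estimates)) NA_integer_
                      else sum(estimates$quality != "ok"),
    filter_order = if (is.null(estimates)) NA_integer_
                   else attr(estimates, "filter_order"),
    a0_sum = if (is.null(estimates)) NA_real_ else attr(estimates, "a0_sum")
  )
  m$config$extinction <- if (is.null(config$extinction)) "embedded-default"
                         else as.numeric(t(config$extinction$eps))
  class(m) <- "run_manifest"
  m
}

#' Write a run manifest as JSON
#'
#' @param manifest a `run_manifest`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
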