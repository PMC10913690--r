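#' Construct a two-channel PPG record
#'
#' A `ppg_record` holds uniformly sampled light-intensity samples for two
#' wavelength channels. Times are seconds from session start on a uniform
#' grid; intensities are nonnegative detector units.
#'
#' @param times sample times in seconds, strictly increasing, uniform to
#'   within 1e-6 s of `1/sample_rate`.
#' @param channel_a,channel_b intensity samples, same length as `times`.
#' @param sample_rate sampling rate in Hz; inferred from `times` if missing.
#' @param labels length-2 character, per-channel wavelength/color tags.
#' @return an object of class `ppg_record`.
#' @export
ppg_record <- function(times, channel_a, channel_b, sample_rate = NULL,
                       labels = c("650nm", "930nm")) {
  times <- as.numeric(times)
  channel_a <- as.numeric(channel_a)
  channel_b <- as.numeric(channel_b)
  n <- length(times)
  if (length(channel_a) != n || length(channel_b) != n) {
    stop("format error: channel lengths differ from time vector")
  }
  if (n < 2) stop("format error: need at least 2 samples")
  dt <- diff(times)
  if (any(dt <= 0)) stop("format error: times must be strictly increasing")
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(dt)
  if (any(abs(dt - 1 / sample_rate) > 1e-6)) {
    stop("sampling error: non-uniform sampling beyond 1e-6 s tolerance")
  }
  if (any(!is.finite(channel_a)) || any(!is.finite(channel_b))) {
    stop("format error: non-finite intensity values")
  }
  if (any(channel_a < 0) || any(channel_b < 0)) {
    stop("validation error: negative intensity values")
  }
  structure(
    list(times = times, channel_a = channel_a, channel_b = channel_b,
         sample_rate = sample_rate, labels = as.character(labels)),
    class = "ppg_record"
  )
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %d samples @ %g Hz (%.1f s), channels %s\n",
              length(x$times), x$sample_rate,
              length(x$times) / x$sample_rate,
              paste(x$labels, collapse = " / ")))
  invisible(x)
}

#' @export
length.ppg_record <- function(x) length(x$times)

#' Read a two-channel PPG CSV
#'
#' Expects header `time_s,ch_a,ch_b`. If the config's polarity flag is
#' `"inverted"` (ADC counts growing at systole) the channels are mapped back
#' to intensity orientation by reflecting about the channel maximum.
#'
#' @param path CSV file path.
#' @param config a [pipeline_config()]; controls polarity and labels.
#' @return a [ppg_record()].
#' @export
read_ppg_csv <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "ch_a", "ch_b")
  if (!all(need %in% names(df))) {
    stop("format error: PPG CSV must have columns ", paste(need, collapse = ", "))
  }
  a <- df$ch_a
  b <- df$ch_b
  if (config$polarity == "inverted") {
    a <- max(a) + min(a) - a
    b <- max(b) + min(b) - b
  }
  ppg_record(df$time_s, a, b,
             labels = paste0(config$wavelengths, "nm"))
}

#' Construct / read a reference glucose series
#'
#' @param times times in seconds, strictly increasing.
#' @param values glucose in mg/dL, strictly positive.
#' @param delay_s constant sensor delay in seconds (0 for none).
#' @return an object of class `glucose_series`.
#' @export
glucose_series <- function(times, values, delay_s = 0) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) == 0) stop("format error: empty glucose series")
  if (length(times) != length(values)) {
    stop("format error: glucose times/values length mismatch")
  }
  if (any(diff(times) <= 0)) {
    stop("format error: glucose times must be strictly increasing")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("format error: glucose values must be positive")
  }
  structure(list(times = times, values = values, delay_s = as.numeric(delay_s)),
            class = "glucose_series")
}

#' @rdname glucose_series
#' @param path CSV with header `time_s,glucose_mgdl`.
#' @export
read_glucose_csv <- function(path, delay_s = 0) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("format error: ", conditionMessage(e)))
  need <- c("time_s", "glucose_mgdl")
  if (nrow(df) == 0 || !all(need %in% names(df))) {
    stop("format error: glucose CSV must have columns ",
         paste(need, collapse = ", "), " and at least one row")
  }
  glucose_series(df$time_s, df$glucose_mgdl, delay_s = delay_s)
}

#' @export
print.glucose_series <- function(x, ...) {
  cat(sprintf("<glucose_series> %d points, %.0f-%.0f mg/dL, delay %g s\n",
              length(x$times), min(x$values), max(x$values), x$delay_s))
  invisible(x)
}

#' Write per-window results to CSV
#'
#' Columns `time_s,mi,mi_corrected,sao2,dtheta_rad,quality`. Values are
#' written with 9 significant digits so a write/read cycle round-trips to
#' 1e-9 relative. Rows whose estimate is not finite are emitted with empty
#' numeric cells and quality `"rejected"`.
#'
#' @param estimates a data frame of window estimates (see [process_ppg()]),
#'   or anything with columns `time_center`, `mi`, `mi_corrected`, `sao2`,
#'   `dtheta`, `quality`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(estimates, path) {
  df <- as.data.frame(estimates)
  need <- c("time_center", "mi", "mi_corrected", "sao2", "dtheta", "quality")
  if (!all(need %in% names(df))) {
    stop("format error: estimates must have columns ", paste(need, collapse = ", "))
  }
  bad <- !is.finite(df$mi) | !is.finite(df$sao2) | !is.finite(df$dtheta)
  quality <- as.character(df$quality)
  quality[bad] <- "rejected"
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.12g", v), "")
  out <- data.frame(
    time_s = fmt(df$time_center),
    mi = fmt(df$mi),
    mi_corrected = fmt(df$mi_corrected),
    sao2 = fmt(df$sao2),
    dtheta_rad = fmt(df$dtheta),
    quality = quality,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  invisible(path)
}

#' Read a results CSV written by [write_results_csv()]
#'
#' @param path CSV file path.
#' @return data frame with columns `time_center`, `mi`, `mi_corrected`,
#'   `sao2`, `dtheta`, `quality`.
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(quality = "character"))
  need <- c("time_s", "mi", "mi_corrected", "sao2", "dtheta_rad", "quality")
  if (!all(need %in% names(df))) {
    stop("format error: results CSV must have columns ",
         paste(need, collapse = ", "))
  }
  data.frame(
    time_center = as.numeric(df$time_s),
    mi = as.numeric(df$mi),
    mi_corrected = as.numeric(df$mi_corrected),
    sao2 = as.numeric(df$sao2),
    dtheta = as.numeric(df$dtheta_rad),
    quality = df$quality,
    stringsAsFactors = FALSE
  )
}
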