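# Back half of the pipeline: per-minute chunking with outlier removal,
# Savitzky-Golay smoothing, interpolation onto reference timestamps and
# reference-delay compensation.

#' Chunk window estimates and average with outlier rejection
#'
#' Values are divided into consecutive chunks of `chunk_s` seconds; within
#' each chunk, quality-`"ok"` values outside the `k * IQR` fences are
#' rejected and the mean of the remainder is taken. A chunk whose rejected
#' fraction exceeds `max_frac`, or that holds no usable value, is marked
#' missing rather than averaged from a minority.
#'
#' @param times numeric times (s) of the per-window values, sorted.
#' @param values numeric values (MI or MI').
#' @param quality character quality flags; only `"ok"` values enter.
#' @param chunk_s chunk length in seconds.
#' @param k IQR fence multiplier.
#' @param max_frac maximum rejected fraction before the chunk goes missing.
#' @return data frame of class `mi_series`: `time_s` (chunk centers), `raw`
#'   (chunk means, NA = missing), `n`, `n_rejected`.
#' @export
chunk_and_average <- function(times, values, quality = NULL, chunk_s = 60,
                              k = 1.5, max_frac = 0.4) {
  stopifnot(length(times) == length(values))
  if (is.unsorted(times)) stop("format error: times must be sorted")
  if (is.null(quality)) quality <- rep("ok", length(values))
  usable <- quality == "ok" & is.finite(values)
  idx <- floor(times / chunk_s)
  chunks <- seq(min(idx), max(idx))
  raw <- rep(NA_real_, length(chunks))
  n_in <- integer(length(chunks))
  n_rej <- integer(length(chunks))
  for (ci in seq_along(chunks)) {
    sel <- idx == chunks[ci] & usable
    v <- values[sel]
    n_in[ci] <- length(v)
    if (length(v) == 0) next
    keep <- rep(TRUE, length(v))
    if (length(v) >= 4) {
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      keep <- v >= q[1] - k * iqr & v <= q[2] + k * iqr
    }
    n_rej[ci] <- sum(!keep)
    if (n_rej[ci] / length(v) > max_frac) next  # chunk stays missing
    raw[ci] <- mean(v[keep])
  }
  if (all(is.na(raw))) stop("insufficient-data error: all chunks empty")
  out <- data.frame(time_s = (chunks + 0.5) * chunk_s, raw = raw,
                    n = n_in, n_rejected = n_rej)
  class(out) <- c("mi_series", "data.frame")
  out
}

# bridge interior NA runs of length <= max_gap by linear interpolation;
# longer runs and edge NAs stay missing
bridge_gaps <- function(x, times, max_gap = 3) {
  ok <- which(is.finite(x))
  if (length(ok) < 2) return(x)
  r <- rle(!is.finite(x))
  pos <- cumsum(c(1, r$lengths))
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    s <- pos[i]; e <- pos[i] + r$lengths[i] - 1
    if (s == 1 || e == length(x)) next           # edge gap: no extrapolation
    if (r$lengths[i] > max_gap) next             # long gap propagates
    x[s:e] <- stats::approx(times[c(s - 1, e + 1)], x[c(s - 1, e + 1)],
                            xout = times[s:e])$y
  }
  x
}

#' Smooth a chunked MI series
#'
#' Bridges interior missing chunks up to `max_gap_chunks` by linear
#' interpolation (longer gaps propagate as missing), then applies the
#' Savitzky-Golay smoother with truncated-window edge handling.
#'
#' @param series an `mi_series` from [chunk_and_average()].
#' @param order,window Savitzky-Golay parameters.
#' @param max_gap_chunks longest bridged gap, in chunks.
#' @return `series` with a `smoothed` column added.
#' @export
smooth_mi_series <- function(series, order = 1, window = 29,
                             max_gap_chunks = 3) {
  x <- bridge_gaps(series$raw, series$time_s, max_gap = max_gap_chunks)
  series$smoothed <- savgol_smooth(x, order = order, window = window)
  series
}

#' Interpolate a series onto target timestamps
#'
#' Linear interpolation, exact at the knots; targets outside the series'
#' time support are returned as `NA` (never extrapolated).
#'
#' @param times,values the series knots (NA values are dropped).
#' @param target_times times to interpolate to.
#' @return values at `target_times` (NA outside support).
#' @export
interpolate_to <- function(times, values, target_times) {
  ok <- is.finite(values)
  if (sum(ok) < 2) return(rep(NA_real_, length(target_times)))
  stats::approx(times[ok], values[ok], xout = target_times, rule = 1)$y
}

#' Compensate a reference sensor delay
#'
#' A reference glucose sensor reading at time `t` reflects blood glucose at
#' `t - delay_s`; shifting the reference times by `-delay_s` aligns the
#' series with the optically measured trend.
#'
#' @param glucose a [glucose_series()].
#' @param delay_s delay in seconds; defaults to the series' own `delay_s`.
#' @return a delay-compensated `glucose_series` (with `delay_s = 0`).
#' @export
compensate_delay <- function(glucose, delay_s = NULL) {
  stopifnot(inherits(glucose, "glucose_series"))
  if (is.null(delay_s)) delay_s <- glucose$delay_s
  if (!is.finite(delay_s)) stop("domain error: delay must be finite")
  glucose_series(glucose$times - delay_s, glucose$values, delay_s = 0)
}
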