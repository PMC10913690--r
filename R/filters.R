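# IIR band-pass design and zero-phase filtering.
#
# No signal-processing package ships with the target environment, so the
# classical Butterworth band-pass chain is implemented here: analog prototype
# -> band-pass transform -> bilinear transform, with the order selected from
# the passband/stopband dB specification, and a forward-backward (zero-phase)
# application with odd-reflection padding.

# polynomial coefficients (descending powers) from roots, kept complex until
# the final real cast
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design a Butterworth band-pass filter from a dB specification
#'
#' The prototype order is the smallest meeting `rs` dB attenuation at the
#' stopband edges given at most `rp` dB loss at the passband edges (single
#' pass); the passband edges are met exactly. Frequencies are prewarped for
#' the bilinear transform so the designed digital response hits the analog
#' specification at the stated edges.
#'
#' @param sample_rate sampling rate in Hz.
#' @param pass,stop passband / stopband edge pairs in Hz.
#' @param rp maximum passband loss in dB.
#' @param rs minimum stopband attenuation in dB.
#' @return list of class `iir_filter` with transfer-function coefficients
#'   `b`, `a`, the selected prototype `order`, and the design spec.
#' @export
design_bandpass <- function(sample_rate, pass = c(0.8, 10), stop = c(0.4, 15),
                            rp = 3, rs = 10) {
  nyq <- sample_rate / 2
  if (pass[2] >= nyq) stop("config error: passband edge at or above Nyquist")
  if (stop[2] >= nyq) stop("config error: stopband edge at or above Nyquist")
  c2 <- 2 * sample_rate
  warp <- function(f) c2 * tan(pi * f / sample_rate)
  wp <- warp(pass); ws <- warp(stop)
  w0sq <- wp[1] * wp[2]
  bw <- wp[2] - wp[1]
  # normalized stopband frequencies under the lowpass->bandpass mapping
  wsn <- abs((ws^2 - w0sq) / (bw * ws))
  wsn <- min(wsn)
  gp <- 10^(rp / 10) - 1
  gs <- 10^(rs / 10) - 1
  order <- ceiling(log10(gs / gp) / (2 * log10(wsn)))
  order <- max(order, 1L)
  # prototype cutoff meeting the passband edge exactly
  wc <- gp^(-1 / (2 * order))
  k <- seq_len(order)
  p_lp <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  gain <- wc^order
  # lowpass (cutoff wc) -> bandpass: s_lp = (s^2 + w0^2) / (bw * s)
  half <- p_lp * bw / 2
  p_bp <- c(half + sqrt(half^2 - w0sq), half - sqrt(half^2 - w0sq))
  z_bp <- rep(0 + 0i, order)
  gain <- gain * bw^order
  # bilinear transform with constant c2
  zd <- (c2 + z_bp) / (c2 - z_bp)
  pd <- (c2 + p_bp) / (c2 - p_bp)
  gain_d <- gain * Re(prod(c2 - z_bp) / prod(c2 - p_bp))
  zd <- c(zd, rep(-1 + 0i, length(p_bp) - length(z_bp)))
  b <- Re(poly_from_roots(zd)) * gain_d
  a <- Re(poly_from_roots(pd))
  structure(list(b = b, a = a, order = as.integer(order),
                 sample_rate = sample_rate,
                 pass = pass, stop = stop, rp = rp, rs = rs),
            class = "iir_filter")
}

#' @export
print.iir_filter <- function(x, ...) {
  cat(sprintf(
    "<iir_filter> Butterworth band-pass, prototype order %d (%d poles), %g-%g Hz @ %g Hz\n",
    x$order, 2 * x$order, x$pass[1], x$pass[2], x$sample_rate))
  invisible(x)
}

# direct-form IIR filter with zero initial state (vectorised via stats::filter)
iir_filter_apply <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward so the net phase response is zero
#' and the amplitude response is squared. The signal is extended at both ends
#' by odd reflection long enough for the filter transient to die out (at
#' least ten time constants of the lowest passband edge).
#'
#' @param filt an `iir_filter` from [design_bandpass()].
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt <- function(filt, x) {
  stopifnot(inherits(filt, "iir_filter"))
  n <- length(x)
  pad <- min(n - 1, max(3 * (length(filt$a) - 1),
                        ceiling(10 * filt$sample_rate / filt$pass[1])))
  if (pad < 1) stop("insufficient-signal error: signal too short to filter")
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_filter_apply(filt$b, filt$a, xe)
  y <- rev(iir_filter_apply(filt$b, filt$a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Band-pass a signal with the configured Butterworth specification
#'
#' Convenience wrapper: designs the filter from `config` (cached per call)
#' and applies it zero-phase. DC and respiration-band content below the
#' passband are removed; content above the passband is attenuated.
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate in Hz.
#' @param config a [pipeline_config()].
#' @return filtered signal.
#' @export
bandpass <- function(x, sample_rate, config = pipeline_config()) {
  filt <- design_bandpass(sample_rate, config$bpf_pass, config$bpf_stop,
                          config$bpf_rp, config$bpf_rs)
  filtfilt(filt, x)
}

#' Savitzky-Golay smoothing with truncated-window edges
#'
#' Least-squares local-polynomial smoothing. Interior points use the full
#' symmetric window; near the series edges the polynomial is fitted on the
#' truncated window rather than on padded (invented) data. `NA` values are
#' excluded from each local fit; a fit with fewer points than `order + 1`
#' yields `NA`. An order-1 smoother reproduces any exactly linear series on
#' the interior.
#'
#' @param x numeric series (may contain `NA`).
#' @param order polynomial order (default 1).
#' @param window odd window length (default 29). If `x` is shorter than
#'   `window` the window shrinks to the largest valid odd length.
#' @return smoothed series, same length as `x`.
#' @export
savgol_smooth <- function(x, order = 1, window = 29) {
  n <- length(x)
  if (window %% 2 == 0) stop("config error: savgol window must be odd")
  if (window <= order) stop("config error: savgol window must exceed order")
  if (n < window) {
    window <- max(order + 1 + (order %% 2 == 0), 3)
    window <- min(window, if (n %% 2 == 1) n else n - 1)
    if (window <= order || window < 1) return(x)
    message(sprintf("savgol: series shorter than window; shrunk to %d", window))
  }
  m <- (window - 1) %/% 2
  out <- rep(NA_real_, n)
  # precompute full-window projection row (value at window center)
  j <- -m:m
  V <- outer(j, 0:order, `^`)
  h_full <- as.numeric(solve(crossprod(V), t(V))[1, ])
  for (i in seq_len(n)) {
    lo <- max(1, i - m); hi <- min(n, i + m)
    xi <- x[lo:hi]
    keep <- is.finite(xi)
    if (hi - lo + 1 == window && all(keep)) {
      out[i] <- sum(h_full * xi)
    } else {
      jj <- (lo:hi)[keep] - i
      if (sum(keep) >= order + 1) {
        Vi <- outer(jj, 0:order, `^`)
        beta <- qr.solve(Vi, xi[keep])
        out[i] <- beta[1]
      }
    }
  }
  out
}
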