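#' Extinction coefficient matrix
#'
#' A 2x2 matrix of molar extinction coefficients eps\[channel, species\] with
#' species order (HbO2, Hb), in 1/(mM cm), tagged with its wavelength labels
#' and logarithm convention. The modified Beer-Lambert law reads
#' `dA(lambda, t) = eps %*% c(N_HbO2(t), N_Hb(t))` per channel, so inverting
#' the matrix maps two-channel absorbance changes to the oxy/deoxy signals.
#'
#' @param eps 2x2 nonnegative numeric matrix, rows = channels, columns =
#'   species (HbO2, Hb).
#' @param wavelengths length-2 numeric wavelength labels (nm).
#' @param log_base 10 (default, decadic) or `exp(1)` for natural-log tables.
#' @return an object of class `extinction_matrix`.
#' @export
extinction_matrix <- function(eps, wavelengths = c(650, 930), log_base = 10) {
  eps <- matrix(as.numeric(eps), 2, 2)
  if (any(!is.finite(eps)) || any(eps < 0)) {
    stop("config error: extinction coefficients must be finite and >= 0")
  }
  d <- det(eps)
  if (abs(d) < 1e-12) {
    stop(sprintf(
      "singular-matrix error: extinction matrix for pair %s nm is singular (|det| = %g)",
      paste(wavelengths, collapse = "/"), abs(d)))
  }
  dimnames(eps) <- list(paste0(wavelengths, "nm"), c("HbO2", "Hb"))
  structure(list(eps = eps, wavelengths = as.numeric(wavelengths),
                 log_base = log_base, condition = kappa(eps, exact = TRUE)),
            class = "extinction_matrix")
}

#' @export
print.extinction_matrix <- function(x, ...) {
  cat(sprintf("<extinction_matrix> %s nm, %s, cond %.3g\n",
              paste(x$wavelengths, collapse = "/"),
              if (x$log_base == 10) "base-10" else "natural log",
              x$condition))
  print(x$eps)
  invisible(x)
}

#' Embedded hemoglobin extinction table
#'
#' The literature-compiled molar extinction coefficients shipped with the
#' package, as a data frame (wavelength_nm, eps_hbo2, eps_hb, units, source).
#' Units are 1/(mM cm) under the base-10 (decadic) absorbance convention.
#'
#' @return data frame of the embedded table.
#' @export
hb_extinction_table <- function() {
  path <- system.file("extdata", "hb_extinction.csv", package = "hemophase")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default extinction matrix for a supported wavelength pair
#'
#' Returns the embedded literature coefficients for the supported pair
#' (650/930 nm). Any other pair must supply explicit values through
#' [extinction_matrix()] — in particular the pseudo-visible (camera
#' red/blue) mode, whose optimized matrix is a user input.
#'
#' @param wavelengths length-2 numeric pair in nm.
#' @return an [extinction_matrix()].
#' @export
default_extinction <- function(wavelengths = c(650, 930)) {
  if (length(wavelengths) != 2 || wavelengths[1] == wavelengths[2]) {
    stop("config error: need two distinct wavelengths (duplicate pair is singular)")
  }
  tab <- hb_extinction_table()
  idx <- match(wavelengths, tab$wavelength_nm)
  if (any(is.na(idx))) {
    stop("config error: no embedded extinction values for pair ",
         paste(wavelengths, collapse = "/"),
         " nm; supply an explicit matrix in the config")
  }
  extinction_matrix(cbind(tab$eps_hbo2[idx], tab$eps_hb[idx]),
                    wavelengths = wavelengths, log_base = 10)
}

#' Absorbance change of a PPG record
#'
#' Under the modified Beer-Lambert law the absorbance change relative to a
#' per-channel reference intensity is
#' `dA(lambda, t) = -log(Iout(lambda, t) / Iref(lambda))` in the configured
#' log base. The reference convention only shifts `dA` by a constant; the
#' pipeline consumes AC content exclusively, so the default reference is the
#' per-channel mean over the record.
#'
#' @param record a [ppg_record()]; intensities must be strictly positive.
#' @param reference length-2 positive reference intensities; defaults to the
#'   per-channel means.
#' @param log_base 10 (default) or `exp(1)`.
#' @return list with `times` and a 2-column matrix `delta_a` (channels a, b).
#' @export
absorbance_change <- function(record, reference = NULL, log_base = 10) {
  stopifnot(inherits(record, "ppg_record"))
  if (any(record$channel_a <= 0) || any(record$channel_b <= 0)) {
    stop("domain error: nonpositive intensities cannot be log-transformed")
  }
  if (is.null(reference)) {
    reference <- c(mean(record$channel_a), mean(record$channel_b))
  }
  reference <- as.numeric(reference)
  if (length(reference) != 2 || any(!is.finite(reference)) || any(reference <= 0)) {
    stop("domain error: reference intensities must be two positive numbers")
  }
  da <- cbind(
    -log(record$channel_a / reference[1], base = log_base),
    -log(record$channel_b / reference[2], base = log_base)
  )
  colnames(da) <- c("ch_a", "ch_b")
  list(times = record$times, delta_a = da, log_base = log_base)
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per time point, the 2x2 linear system
#' `eps %*% c(N_HbO2, N_Hb) = dA` mapping two-channel absorbance changes to
#' the oxy/deoxyhemoglobin signals N_HbO2(t), N_Hb(t) — changes in molar
#' concentration times path length (mM cm) relative to the reference
#' instant.
#'
#' @param delta_a output of [absorbance_change()] (or a list with `times`
#'   and 2-column `delta_a`).
#' @param eps an [extinction_matrix()]; its log convention must match the
#'   absorbance's.
#' @return list of class `nirs_signals` with `times`, `n_hbo2`, `n_hb`.
#' @export
invert_mbll <- function(delta_a, eps) {
  stopifnot(inherits(eps, "extinction_matrix"))
  if (!is.null(delta_a$log_base) && delta_a$log_base != eps$log_base) {
    stop("config error: absorbance and extinction log conventions differ")
  }
  da <- delta_a$delta_a
  n <- solve(eps$eps, t(da))  # 2 x N
  structure(list(times = delta_a$times,
                 n_hbo2 = as.numeric(n[1, ]),
                 n_hb = as.numeric(n[2, ])),
            class = "nirs_signals")
}

#' @export
print.nirs_signals <- function(x, ...) {
  cat(sprintf("<nirs_signals> %d samples, HbO2 range %.3g, Hb range %.3g (mM cm)\n",
              length(x$times), diff(range(x$n_hbo2)), diff(range(x$n_hb))))
  invisible(x)
}
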