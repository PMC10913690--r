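# Calibration of MI/MI' to glucose and agreement metrics: Pearson r by
# linear least squares, MARD, RMSE and the Parkes (consensus) error grid for
# type 1 diabetes.

#' Linear least-squares calibration of MI to glucose
#'
#' Ordinary least squares of reference glucose on the index, with the
#' Pearson correlation coefficient. A constant glucose series gives slope 0
#' and r defined as 0; a constant index is a degenerate fit.
#'
#' @param mi_values index values (MI or MI').
#' @param glucose_values paired reference glucose (mg/dL).
#' @return object of class `calibration_fit`: `slope` (mg/dL per MI unit),
#'   `intercept` (mg/dL), `r`, `n`.
#' @export
fit_calibration <- function(mi_values, glucose_values) {
  ok <- is.finite(mi_values) & is.finite(glucose_values)
  x <- mi_values[ok]; y <- glucose_values[ok]
  if (length(x) < 3) stop("insufficient-data error: need >= 3 finite pairs")
  if (stats::var(x) == 0) {
    stop("degenerate-fit error: index has zero variance")
  }
  if (stats::var(y) == 0) {
    fit <- list(slope = 0, intercept = mean(y), r = 0, n = length(x))
  } else {
    slope <- stats::cov(x, y) / stats::var(x)
    fit <- list(slope = slope, intercept = mean(y) - slope * mean(x),
                r = stats::cor(x, y), n = length(x))
  }
  class(fit) <- "calibration_fit"
  fit
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> glucose = %.4g + %.4g * MI  (r = %.3f, n = %d)\n",
    x$intercept, x$slope, x$r, x$n))
  invisible(x)
}

#' Mean absolute relative difference
#'
#' `MARD = mean(|estimate - reference| / reference) * 100`, the standard
#' accuracy metric for glucose monitors, in percent.
#'
#' @param reference reference glucose (mg/dL), strictly positive.
#' @param estimate estimated glucose (mg/dL).
#' @return MARD in percent.
#' @export
mard <- function(reference, estimate) {
  stopifnot(length(reference) == length(estimate))
  if (any(reference <= 0)) stop("domain error: reference must be positive")
  mean(abs(estimate - reference) / reference) * 100
}

#' Root-mean-square error
#'
#' @param reference reference glucose (mg/dL).
#' @param estimate estimated glucose (mg/dL).
#' @return RMSE in mg/dL.
#' @export
rmse <- function(reference, estimate) {
  stopifnot(length(reference) == length(estimate), length(reference) >= 1)
  sqrt(mean((estimate - reference)^2))
}

#' Embedded Parkes type-1 zone boundary vertices
#'
#' The consensus (Parkes) error-grid boundary polylines for type 1 diabetes
#' as published (reference on the x axis, estimate on y, grid corner at
#' 550 mg/dL), shipped as a versioned CSV resource.
#'
#' @return data frame with columns `boundary`, `vertex`, `ref_mgdl`,
#'   `est_mgdl`.
#' @export
parkes_vertices <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "parkes_type1_boundaries.csv",
                          package = "hemophase")
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

# evaluate a boundary polyline at reference values x.
# upper boundaries: defined for all x >= 0, extended past the last vertex by
#   the final segment slope (the published grid stops at 550 mg/dL).
# lower boundaries: start with a vertical segment at their first ref; for
#   x <= first ref the zone does not exist (-Inf), which also sends the
#   vertical boundary segment itself to the lower-risk zone.
polyline_eval <- function(vx, vy, x, side = c("upper", "lower")) {
  side <- match.arg(side)
  out <- rep(NA_real_, length(x))
  if (side == "lower") {
    x0 <- vx[1]
    # drop the bottom of the vertical start so approx() sees unique x
    if (vx[1] == vx[2]) { vx <- vx[-1]; vy <- vy[-1] }
    below <- x <= x0
    out[below] <- -Inf
    sel <- !below
  } else {
    sel <- rep(TRUE, length(x))
  }
  if (any(sel)) {
    m <- length(vx)
    slope_end <- (vy[m] - vy[m - 1]) / (vx[m] - vx[m - 1])
    xi <- x[sel]
    yi <- stats::approx(vx, vy, xout = pmin(xi, vx[m]), rule = 2)$y
    over <- xi > vx[m]
    yi[over] <- vy[m] + slope_end * (xi[over] - vx[m])
    out[sel] <- yi
  }
  out
}

#' Parkes (consensus) error-grid zone for type 1 diabetes
#'
#' Assigns each (reference, estimate) pair to zone A-E by comparison with
#' the embedded boundary polylines. The zones partition \[0, 600\]^2 totally
#' and deterministically; a point exactly on a boundary goes to the
#' lower-risk zone.
#'
#' @param reference,estimate glucose values in mg/dL, each in \[0, 600\].
#' @return character vector of zone labels.
#' @export
parkes_zone <- function(reference, estimate) {
  stopifnot(length(reference) == length(estimate))
  if (any(!is.finite(reference)) || any(!is.finite(estimate)) ||
      any(reference < 0 | reference > 600) ||
      any(estimate < 0 | estimate > 600)) {
    stop("domain error: glucose values must be finite and within [0, 600] mg/dL")
  }
  v <- parkes_vertices()
  bnd <- function(name) v[v$boundary == name, ]
  up <- function(name) {
    b <- bnd(name)
    polyline_eval(b$ref_mgdl, b$est_mgdl, reference, side = "upper")
  }
  lo <- function(name) {
    b <- bnd(name)
    polyline_eval(b$ref_mgdl, b$est_mgdl, reference, side = "lower")
  }
  risk_up <- (estimate > up("ab_upper")) + (estimate > up("bc_upper")) +
    (estimate > up("cd_upper")) + (estimate > up("de_upper"))
  risk_lo <- (estimate < lo("ab_lower")) + (estimate < lo("bc_lower")) +
    (estimate < lo("cd_lower"))
  c("A", "B", "C", "D", "E")[pmax(risk_up, risk_lo) + 1L]
}

#' Evaluate an MI trend against a reference glucose series
#'
#' Interpolates the smoothed index onto the (delay-compensated) reference
#' timestamps, converts it to glucose through the calibration fit (fitted on
#' the same pairs when no fit is supplied, as in a per-subject calibration),
#' and reports correlation, MARD, RMSE and Parkes zone percentages.
#'
#' @param mi_series a smoothed `mi_series` (see [smooth_mi_series()]), or a
#'   data frame with `time_s` and the column named by `value_col`.
#' @param glucose a [glucose_series()]; its `delay_s` is compensated.
#' @param fit optional [fit_calibration()] result to apply; `NULL` fits on
#'   the overlapping pairs.
#' @param value_col column of `mi_series` to evaluate (default
#'   `"smoothed"`).
#' @return object of class `error_grid_result`: `fit`, `zones` (per-point
#'   labels), `zone_percent`, `mard`, `rmse`, `n`, plus the paired
#'   `reference` / `estimate` values and times.
#' @export
evaluate_session <- function(mi_series, glucose, fit = NULL,
                             value_col = "smoothed") {
  stopifnot(inherits(glucose, "glucose_series"))
  ref <- compensate_delay(glucose)
  mi_at_ref <- interpolate_to(mi_series$time_s, mi_series[[value_col]],
                              ref$times)
  ok <- is.finite(mi_at_ref)
  if (sum(ok) < 3) {
    stop("insufficient-data error: fewer than 3 overlapping points")
  }
  mi <- mi_at_ref[ok]
  g <- ref$values[ok]
  if (is.null(fit)) fit <- fit_calibration(mi, g)
  est <- fit$intercept + fit$slope * mi
  est_cl <- pmin(pmax(est, 0), 600)
  zones <- parkes_zone(pmin(g, 600), est_cl)
  zp <- table(factor(zones, levels = c("A", "B", "C", "D", "E")))
  res <- list(
    fit = fit,
    times = ref$times[ok],
    reference = g,
    estimate = est,
    zones = zones,
    zone_percent = 100 * as.numeric(zp) / length(zones),
    mard = mard(g, est),
    rmse = rmse(g, est),
    n = length(g)
  )
  names(res$zone_percent) <- names(zp)
  class(res) <- "error_grid_result"
  res
}

#' @export
print.error_grid_result <- function(x, ...) {
  cat(sprintf("<error_grid_result> n = %d, r = %.3f\n", x$n, x$fit$r))
  cat(sprintf("  MARD %.1f%%, RMSE %.1f mg/dL\n", x$mard, x$rmse))
  zp <- x$zone_percent[x$zone_percent > 0]
  cat("  zones:", paste(sprintf("%s %.1f%%", names(zp), zp), collapse = ", "),
      "\n")
  invisible(x)
}
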