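#' Time-series container
#'
#' Holds concentration trajectories on a common time grid: a numeric
#' matrix with one row per time point and one column per pool. Pools
#' without data (hidden/unmeasurable metabolites) are flagged in
#' `measured`; their columns hold `NA`. `sigma` carries per-point
#' standard deviations for the chi-square weighting and defaults to 1
#' everywhere.
#'
#' @param times strictly increasing numeric vector.
#' @param values numeric matrix, `length(times)` rows, named columns.
#' @param sigma positive matrix like `values`, default all 1.
#' @param measured named logical per column; default: column has any
#'   non-`NA` value.
#' @param dimensionless flag: values are X/X* rather than concentrations.
#' @return object of class `pendisc_timeseries`.
#' @export
timeseries <- function(times, values, sigma = NULL, measured = NULL,
                       dimensionless = FALSE) {
  values <- as.matrix(values)
  stopifnot(length(times) == nrow(values),
            length(times) < 2 || all(diff(times) > 0))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("X", seq_len(ncol(values)))
  if (is.null(measured))
    measured <- apply(values, 2, function(v) any(!is.na(v)))
  measured <- stats::setNames(as.logical(measured), colnames(values))
  if (any(values[, measured, drop = FALSE] <= 0, na.rm = TRUE))
    stop("concentration values must be positive")
  sigma_supplied <- !is.null(sigma)
  if (!sigma_supplied) sigma <- matrix(1, nrow(values), ncol(values))
  sigma <- as.matrix(sigma)
  stopifnot(all(dim(sigma) == dim(values)), all(sigma > 0, na.rm = TRUE))
  dimnames(sigma) <- dimnames(values)
  structure(list(times = as.numeric(times), values = values, sigma = sigma,
                 sigma_supplied = sigma_supplied,
                 measured = measured, dimensionless = dimensionless),
            class = "pendisc_timeseries")
}

#' @export
print.pendisc_timeseries <- function(x, ...) {
  cat("pendisc time series: ", length(x$times), " points on [",
      format(min(x$times)), ", ", format(max(x$times)), "], ",
      sum(x$measured), "/", length(x$measured), " pools measured",
      if (x$dimensionless) " (dimensionless)", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.pendisc_timeseries <- function(x, ...) {
  data.frame(time = x$times, x$values, check.names = FALSE)
}

#' Rescale a dimensional time series by steady-state values
#'
#' Divides each measured pool's trajectory by the pool's steady-state
#' concentration, producing the dimensionless series x = X/X* that the
#' fitting operates on. A user-supplied sigma is propagated on the same
#' scale; the default all-ones sigma stays all-ones (unweighted
#' residuals in dimensionless space).
#'
#' @param ts a dimensional `pendisc_timeseries`.
#' @param X_star named positive vector covering at least the measured pools.
#' @return dimensionless `pendisc_timeseries`.
#' @export
to_dimensionless <- function(ts, X_star) {
  stopifnot(inherits(ts, "pendisc_timeseries"), !ts$dimensionless)
  vals <- ts$values
  sg <- if (isTRUE(ts$sigma_supplied)) ts$sigma else NULL
  for (p in colnames(vals)[ts$measured]) {
    if (!p %in% names(X_star) || !is.finite(X_star[p]))
      stop("no steady-state value for measured pool '", p, "'")
    vals[, p] <- vals[, p] / X_star[p]
    if (!is.null(sg)) sg[, p] <- sg[, p] / X_star[p]
  }
  timeseries(ts$times, vals, sg, ts$measured, dimensionless = TRUE)
}
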