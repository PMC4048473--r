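#' Inject bounded multiplicative noise into a time series
#'
#' Each measured value is multiplied by (1 + u), u drawn independently
#' and uniformly from \[-level, +level\] — noise "up to" the stated
#' fraction, with a hard bound, so values never change sign. A Gaussian
#' alternative (sd = level, truncated at +/- 3 sd to preserve
#' positivity for level < 1/3) is available behind a flag.
#'
#' @param ts a [timeseries()].
#' @param level relative noise bound in `[0, 1)`.
#' @param seed optional RNG seed (recorded as an attribute).
#' @param distribution `"uniform"` (default) or `"gaussian"`.
#' @return a noisy `pendisc_timeseries`.
#' @export
add_noise <- function(ts, level, seed = NULL,
                      distribution = c("uniform", "gaussian")) {
  stopifnot(inherits(ts, "pendisc_timeseries"), level >= 0, level < 1)
  distribution <- match.arg(distribution)
  if (level == 0) return(ts)
  if (!is.null(seed)) set.seed(seed)
  u <- if (distribution == "uniform")
    stats::runif(length(ts$values), -level, level)
  else pmax(pmin(stats::rnorm(length(ts$values), 0, level), 3 * level),
            -3 * level)
  vals <- ts$values * (1 + u)
  out <- timeseries(ts$times, vals,
                    if (isTRUE(ts$sigma_supplied)) ts$sigma,
                    ts$measured, ts$dimensionless)
  attr(out, "noise") <- list(level = level, seed = seed,
                             distribution = distribution)
  out
}

#' Estimate steady-state concentrations from data
#'
#' Averages the last `k_last` points of each measured pool — the data
#' in the neighborhood of the steady state — giving the experimental
#' steady-state concentration used for non-dimensionalization when the
#' true value is unknown.
#'
#' @param ts a [timeseries()].
#' @param k_last number of trailing points to average (default 5).
#' @return named vector over measured pools.
#' @export
steady_states_from_data <- function(ts, k_last = 5) {
  stopifnot(inherits(ts, "pendisc_timeseries"),
            length(ts$times) >= k_last, k_last >= 1)
  idx <- seq(nrow(ts$values) - k_last + 1, nrow(ts$values))
  meas <- names(ts$measured)[ts$measured]
  vapply(meas, function(p) mean(ts$values[idx, p]), numeric(1))
}

#' Dimensionless mean squared error of a fit against reference data
#'
#' Integrates the fitted dimensionless model over the reference time
#' grid (from the reference's own first state) and averages the squared
#' dimensionless residuals jointly over all measured pools and time
#' points.
#'
#' @param fit a `pendisc_fit` (or a `pendisc_dimensionless` model).
#' @param reference a [timeseries()]; dimensional data are rescaled by
#'   `X_star`.
#' @param X_star steady-state vector for rescaling; defaults to the
#'   fit's.
#' @return scalar MSE.
#' @export
mse <- function(fit, reference, X_star = NULL) {
  model <- if (inherits(fit, "pendisc_fit")) fit$model else fit
  stopifnot(inherits(model, "pendisc_dimensionless"),
            inherits(reference, "pendisc_timeseries"))
  if (!reference$dimensionless) {
    if (is.null(X_star))
      X_star <- if (inherits(fit, "pendisc_fit")) fit$X_star else model$X_star
    reference <- to_dimensionless(reference, X_star)
  }
  meas <- names(reference$measured)[reference$measured]
  x0 <- stats::setNames(rep(1, model$network$n), model$network$pools$name)
  x0[meas] <- reference$values[1, meas]
  if (inherits(fit, "pendisc_fit") && length(fit$hidden))
    x0[fit$hidden] <- fit$hidden_x0
  sim <- simulate_model(model, x0, reference$times,
                        rtol = 1e-8, atol = 1e-10)
  resid <- reference$values[, meas, drop = FALSE] -
    sim$values[, meas, drop = FALSE]
  mean(resid^2)
}

#' Leave-one-out cross-validation of a fit
#'
#' Removes one time point at a time — across all pools simultaneously —
#' refits, and records the refit's parameters and its dimensionless MSE
#' against the full data. A per-pool removal variant (each pool losing
#' the point independently while others keep it) is available.
#'
#' @param data a [timeseries()].
#' @param network a [pathway_network()].
#' @param ... passed to [lm_fit()] / [fit_with_hidden_pools()]
#'   (order policy, `X_star`, `config`, ...).
#' @param mode `"all_pools"` (default: the time index is dropped for
#'   every pool) or `"per_pool"`.
#' @param skip_first keep the first time point in every refit (it
#'   anchors the initial state); default TRUE.
#' @return object of class `pendisc_loo`: `mse_all`, `mse_per_removal`
#'   (named by removed time), `fits`, `failures`.
#' @export
loo_cv <- function(data, network, ..., mode = c("all_pools", "per_pool"),
                   skip_first = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(data$times) >= 3)
  fit_all <- lm_fit(data, network, ...)
  mse_all <- mse(fit_all, data)
  drop_idx <- seq_along(data$times)
  if (skip_first) drop_idx <- drop_idx[-1]
  removals <- if (mode == "all_pools") {
    lapply(drop_idx, function(k) list(k = k, pool = NULL,
                                      key = format(data$times[k])))
  } else {
    meas <- names(data$measured)[data$measured]
    do.call(c, lapply(drop_idx, function(k)
      lapply(meas, function(p)
        list(k = k, pool = p,
             key = paste0(p, "@", format(data$times[k]))))))
  }
  per <- list(); fits <- list(); failures <- list()
  for (rm in removals) {
    res <- try({
      if (is.null(rm$pool)) {
        red <- timeseries(data$times[-rm$k],
                          data$values[-rm$k, , drop = FALSE],
                          if (isTRUE(data$sigma_supplied))
                            data$sigma[-rm$k, , drop = FALSE],
                          data$measured, data$dimensionless)
      } else {
        # keep the grid; weight the removed point out via infinite sigma
        red <- data
        red$sigma[rm$k, rm$pool] <- Inf
      }
      lm_fit(red, network, ...)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failures[[rm$key]] <- as.character(res)
    } else {
      fits[[rm$key]] <- res
      per[[rm$key]] <- mse(res, data)
    }
  }
  structure(list(mse_all = mse_all,
                 mse_per_removal = unlist(per),
                 fit_all = fit_all, fits = fits, failures = failures),
            class = "pendisc_loo")
}

#' @export
print.pendisc_loo <- function(x, ...) {
  cat("leave-one-out cross-validation:", length(x$mse_per_removal),
      "removals,", length(x$failures), "failures\n")
  cat("  all-data MSE:", format(x$mse_all), "\n")
  cat("  removal MSE range: [", format(min(x$mse_per_removal)), ", ",
      format(max(x$mse_per_removal)), "]\n", sep = "")
  invisible(x)
}

#' Perturbation-response prediction
#'
#' Starts the dimensionless model at its steady state with one pool
#' scaled by `factor` (e.g. doubled) and integrates until every pool is
#' back within `return_tol` (relative) of the steady state, or the
#' horizon is reached.
#'
#' @param model a `pendisc_dimensionless` (e.g. `fit$model`).
#' @param pool name of the perturbed pool.
#' @param factor multiplicative perturbation (default 2).
#' @param return_tol relative band around the steady state that counts
#'   as "returned" (default 0.001).
#' @param horizon maximum integration time.
#' @param n_points output grid size.
#' @return a dimensionless [timeseries()] with attribute `returned`
#'   (logical) and `return_time`.
#' @export
perturbation_response <- function(model, pool, factor = 2,
                                  return_tol = 1e-3, horizon = 200,
                                  n_points = 201) {
  stopifnot(inherits(model, "pendisc_dimensionless"),
            pool %in% model$network$pools$name, factor > 0)
  x0 <- stats::setNames(rep(1, model$network$n), model$network$pools$name)
  x0[pool] <- factor
  t_hi <- 5
  repeat {
    times <- seq(0, t_hi, length.out = n_points)
    ts <- simulate_model(model, x0, times, rtol = 1e-9, atol = 1e-11)
    dev <- apply(abs(ts$values - 1), 1, max)
    back <- which(dev < return_tol)
    if (length(back) && max(dev[seq(min(back), length(dev))]) < return_tol) {
      attr(ts, "returned") <- TRUE
      attr(ts, "return_time") <- times[min(back)]
      return(ts)
    }
    if (t_hi >= horizon) {
      attr(ts, "returned") <- FALSE
      attr(ts, "return_time") <- NA_real_
      warning("no return to steady state within horizon ", horizon)
      return(ts)
    }
    t_hi <- min(t_hi * 2, horizon)
  }
}
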