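#' Fitting configuration
#'
#' Controls for the Levenberg-Marquardt estimation. The defaults mirror a
#' deliberately spartan protocol: every free constant starts at 5, and
#' iteration stops when an accepted step satisfies both
#' `(chi2_old - chi2_new)/chi2_old <= rel_tol` and `chi2_new <= abs_chi2_tol`.
#' The absolute criterion is only attainable on (near) noise-free data;
#' for noisy data a documented fallback declares convergence when the
#' relative criterion alone holds on 5 consecutive accepted steps.
#'
#' @param initial_guess scalar (recycled) or vector of positive starting
#'   values for the free parameters; default 5.
#' @param rel_tol relative chi-square decrease threshold (1e-8).
#' @param abs_chi2_tol absolute chi-square threshold (1e-5).
#' @param max_iterations LM iteration cap.
#' @param lm_lambda0 initial damping parameter.
#' @param lm_factor damping multiplier on reject / divisor on accept.
#' @param derivative_scheme `"central_richardson"` (default) or
#'   `"forward"` for the residual Jacobian.
#' @param ode_rtol,ode_atol integrator tolerances used inside the fit.
#' @param log_params optimize in log-parameter space instead of rejecting
#'   non-positive steps (off by default; plain LM with step rejection).
#' @param seed optional integer recorded in results.
#' @return object of class `pendisc_fit_config`.
#' @export
fit_config <- function(initial_guess = 5, rel_tol = 1e-8,
                       abs_chi2_tol = 1e-5, max_iterations = 500,
                       lm_lambda0 = 1e-3, lm_factor = 10,
                       derivative_scheme = c("central_richardson", "forward"),
                       ode_rtol = 1e-8, ode_atol = 1e-10,
                       log_params = FALSE, seed = NULL) {
  stopifnot(all(initial_guess > 0), rel_tol > 0, abs_chi2_tol > 0,
            max_iterations >= 1, lm_lambda0 > 0, lm_factor > 1,
            ode_rtol > 0, ode_atol > 0)
  structure(list(initial_guess = initial_guess, rel_tol = rel_tol,
                 abs_chi2_tol = abs_chi2_tol,
                 max_iterations = as.integer(max_iterations),
                 lm_lambda0 = lm_lambda0, lm_factor = lm_factor,
                 derivative_scheme = match.arg(derivative_scheme),
                 ode_rtol = ode_rtol, ode_atol = ode_atol,
                 log_params = log_params, seed = seed),
            class = "pendisc_fit_config")
}

# Assemble the objective machinery shared by chi_square, lm_fit and
# fit_with_hidden_pools. Parameter vector layout:
#   [A_f for measured free pools | Y_f for hidden free pools |
#    A_h for every hidden pool]
# Measured pools get A_i = Y_i / X_i*; hidden pools keep their own A_h
# parameter; their steady state is recovered afterwards as Y_h / A_h.
make_objective <- function(network, g, h, cs, data, hidden_x0 = NULL,
                           ode_rtol = 1e-8, ode_atol = 1e-10) {
  stopifnot(inherits(data, "pendisc_timeseries"), data$dimensionless)
  nm <- network$pools$name
  measured <- nm[nm %in% names(data$measured)[data$measured]]
  hidden <- setdiff(nm, measured)
  free_meas <- intersect(cs$free, measured)
  free_hid <- intersect(cs$free, hidden)
  par_names <- c(paste0("A_", free_meas),
                 if (length(free_hid)) paste0("Y_", free_hid),
                 if (length(hidden)) paste0("A_", hidden))
  n_par <- length(par_names)
  if (!length(measured))
    stop("no measured pools: nothing to fit against")
  n_res_pts <- length(data$times) * length(measured)
  if (n_par > n_res_pts)
    stop("under-determined fit: ", n_par, " parameters (",
         length(hidden), " hidden pool(s)) against only ", n_res_pts,
         " residuals; measure more pools or supply steady states")

  x0 <- stats::setNames(rep(NA_real_, length(nm)), nm)
  x0[measured] <- data$values[1, measured]
  if (length(hidden)) {
    if (is.null(hidden_x0)) hidden_x0 <- stats::setNames(rep(1, length(hidden)), hidden)
    if (is.null(names(hidden_x0)) && length(hidden_x0) == length(hidden))
      names(hidden_x0) <- hidden
    x0[hidden] <- hidden_x0[hidden]
  }
  if (anyNA(x0)) stop("missing initial state for pool(s): ",
                      paste(nm[is.na(x0)], collapse = ", "))

  split_par <- function(theta) {
    i <- 0
    Af <- stats::setNames(theta[seq_along(free_meas)], free_meas)
    i <- length(free_meas)
    Yf <- stats::setNames(theta[i + seq_along(free_hid)], free_hid)
    i <- i + length(free_hid)
    Ah <- stats::setNames(theta[i + seq_along(hidden)], hidden)
    list(Af = Af, Yf = Yf, Ah = Ah)
  }

  expand <- function(theta) {
    if (any(theta <= 0)) infeasible("non-positive parameter")
    sp <- split_par(theta)
    freeY <- stats::setNames(numeric(length(cs$free)), cs$free)
    freeY[free_meas] <- cs$X_star[free_meas] * sp$Af
    freeY[free_hid] <- sp$Yf
    Y <- expand_composites(freeY, cs)
    A <- stats::setNames(rep(NA_real_, length(nm)), nm)
    A[measured] <- Y[measured] / cs$X_star[measured]
    A[hidden] <- sp$Ah
    if (any(A <= 0)) infeasible("expanded rate constant non-positive")
    Xs_est <- if (length(hidden)) Y[hidden] / sp$Ah else numeric(0)
    list(A = A, Y = Y, X_star_est = Xs_est)
  }

  residuals_fn <- function(theta) {
    ex <- expand(theta)
    mod <- dimensionless_model(network, ex$A, g, h, X_star = ifelse(
      is.na(cs$X_star), 1, cs$X_star))
    out <- try(deSolve::lsoda(y = x0, times = data$times,
                              func = dimensionless_rhs(mod), parms = NULL,
                              rtol = ode_rtol, atol = ode_atol), silent = TRUE)
    if (inherits(out, "try-error") || attr(out, "istate")[1] < 0 ||
        any(!is.finite(out[, -1])))
      infeasible("trajectory integration failed")
    pred <- out[, measured, drop = FALSE]
    r <- (data$values[, measured, drop = FALSE] - pred) /
      data$sigma[, measured, drop = FALSE]
    as.vector(r)
  }

  unweighted_mse <- function(theta) {
    ex <- expand(theta)
    mod <- dimensionless_model(network, ex$A, g, h, X_star = ifelse(
      is.na(cs$X_star), 1, cs$X_star))
    out <- deSolve::lsoda(y = x0, times = data$times,
                          func = dimensionless_rhs(mod), parms = NULL,
                          rtol = ode_rtol, atol = ode_atol)
    mean((data$values[, measured, drop = FALSE] -
            out[, measured, drop = FALSE])^2)
  }

  list(par_names = par_names, n_par = n_par, expand = expand,
       residuals = residuals_fn, measured = measured, hidden = hidden,
       x0 = x0, mse = unweighted_mse,
       chi2 = function(theta) {
         r <- tryCatch(residuals_fn(theta),
                       pendisc_infeasible = function(e) NULL)
         if (is.null(r)) Inf else sum(r^2)
       })
}

#' Chi-square objective for a parameter vector
#'
#' Expands the free parameters through the constraint set, integrates the
#' dimensionless S-system from the data's first time point, and sums the
#' squared sigma-weighted residuals over measured pools and all time
#' points: chi2 = sum_k [(x_data - x_model)/sigma]^2. Infeasible
#' expansions or failed integrations return `Inf` (the optimizer rejects
#' such steps).
#'
#' @param params free parameter vector (see [lm_fit()] for the layout
#'   when hidden pools are present).
#' @param data dimensionless [timeseries()].
#' @param skeleton `pendisc_ssystem` skeleton carrying the kinetic orders
#'   (from [build_ssystem()]).
#' @param cs matching [derive_constraints()] result.
#' @param hidden_x0 named dimensionless initial values for hidden pools
#'   (default 1).
#' @param ode_rtol,ode_atol integrator tolerances.
#' @return scalar chi-square value (possibly `Inf`).
#' @export
chi_square <- function(params, data, skeleton, cs, hidden_x0 = NULL,
                       ode_rtol = 1e-8, ode_atol = 1e-10) {
  obj <- make_objective(skeleton$network, skeleton$g, skeleton$h, cs, data,
                        hidden_x0, ode_rtol, ode_atol)
  obj$chi2(as.numeric(params))
}

# Core Levenberg-Marquardt loop on a residual function, Press-style
# damping of the normal equations, positivity (and any feasibility the
# residual function enforces) by step rejection.
lm_core <- function(resid_fn, theta0, config) {
  theta <- as.numeric(theta0)
  if (config$log_params) {
    # optimize in u = log(theta); positivity is then structural
    inner <- resid_fn
    resid_fn <- function(u) inner(exp(u))
    theta <- log(theta)
  }
  safe_resid <- function(th) {
    tryCatch(resid_fn(th), pendisc_infeasible = function(e) NULL)
  }
  resid_for_jac <- function(th) {
    r <- safe_resid(th)
    if (is.null(r)) rep(NA_real_, n_res) else r
  }
  r <- safe_resid(theta)
  if (is.null(r)) stop("initial parameter vector is infeasible; cannot start")
  n_res <- length(r)
  chi2 <- sum(r^2)
  trace <- chi2
  lambda <- config$lm_lambda0
  converged <- FALSE
  criterion <- "max_iterations"
  consec_rel <- 0L
  iter <- 0L
  jac <- function(th) {
    if (config$derivative_scheme == "forward") {
      f0 <- resid_for_jac(th)
      J <- vapply(seq_along(th), function(i) {
        hstep <- max(1e-7 * abs(th[i]), 1e-9)
        t2 <- th; t2[i] <- t2[i] + hstep
        (resid_for_jac(t2) - f0) / hstep
      }, numeric(n_res))
      matrix(J, nrow = n_res)
    } else num_jacobian(resid_for_jac, th)
  }
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    J <- jac(theta)
    JtJ <- crossprod(J)
    grad <- crossprod(J, r)
    accepted <- FALSE
    repeat {
      D <- diag(pmax(diag(JtJ), 1e-30), nrow = nrow(JtJ))
      step <- tryCatch(solve(JtJ + lambda * D, -grad),
                       error = function(e) NULL)
      if (!is.null(step)) {
        theta_new <- theta + as.vector(step)
        ok <- config$log_params || all(theta_new > 0)
        if (ok) {
          r_new <- safe_resid(theta_new)
          if (!is.null(r_new) && all(is.finite(r_new))) {
            chi2_new <- sum(r_new^2)
            if (chi2_new < chi2) {
              rel_dec <- (chi2 - chi2_new) / chi2
              theta <- theta_new; r <- r_new; chi2 <- chi2_new
              trace <- c(trace, chi2)
              lambda <- max(lambda / config$lm_factor, 1e-12)
              accepted <- TRUE
              if (rel_dec <= config$rel_tol) {
                consec_rel <- consec_rel + 1L
                if (chi2 <= config$abs_chi2_tol) {
                  converged <- TRUE; criterion <- "relative_and_absolute"
                } else if (consec_rel >= 5L) {
                  converged <- TRUE; criterion <- "relative_sustained"
                }
              } else consec_rel <- 0L
              break
            }
          }
        }
      }
      lambda <- lambda * config$lm_factor
      if (lambda > 1e12) break
    }
    if (!accepted) {
      # no acceptable step at any damping: the chi-square decrease is
      # identically zero from here, i.e. the sustained-relative
      # criterion holds in the limit at this local minimum
      converged <- TRUE
      criterion <- if (chi2 <= config$abs_chi2_tol)
        "relative_and_absolute" else "relative_sustained"
      break
    }
    if (converged) break
  }
  if (config$log_params) theta <- exp(theta)
  list(theta = theta, chi2 = chi2, chi2_trace = trace, iterations = iter,
       converged = converged, criterion = criterion)
}

#' Fit free dimensionless rate constants by Levenberg-Marquardt
#'
#' The estimation core: integrates the dimensionless S-system for trial
#' free rate constants (expanded to the full vector through the
#' structural constraints) and minimizes the chi-square misfit to the
#' data. Damping follows the classic scheme (lambda scaled by
#' `lm_factor` down on accepted steps, up on rejections); steps that
#' leave the positive orthant or make a derived constant non-positive
#' are rejected. After convergence the full vector is expanded,
#' back-transformed to dimensional alpha/beta, and the dimensionless
#' mean squared error against the data is recorded.
#'
#' All pools must be measured here; use [fit_with_hidden_pools()] when
#' some are not.
#'
#' @param data a [timeseries()]; dimensional data are rescaled with
#'   `X_star` internally.
#' @param network a [pathway_network()].
#' @param order_policy,c,g,h kinetic-order policy, as [build_ssystem()].
#' @param X_star steady-state concentrations (named vector); defaults to
#'   the entries stored in `cs`.
#' @param cs constraint set; derived from the network and `X_star` when
#'   omitted.
#' @param config a [fit_config()].
#' @return object of class `pendisc_fit`: elements `free_A`, `full_A`,
#'   `alpha`, `beta`, `X_star`, `X_star_estimated`, `chi2`, `chi2_trace`,
#'   `iterations`, `converged`, `criterion`, `mse`, `model` (the fitted
#'   dimensionless model), `config`, `cs`, `hidden`.
#' @examples
#' \donttest{
#' fx <- branched_reference()
#' ts <- generate_timeseries(fx, n_points = 11)
#' fit <- lm_fit(ts, fx$network, order_policy = "fixed_half",
#'               X_star = fx$X_star)
#' fit$free_A
#' }
#' @export
lm_fit <- function(data, network, order_policy = "fixed_half", c = 0.5,
                   g = NULL, h = NULL, X_star = NULL, cs = NULL,
                   config = fit_config()) {
  prep <- prepare_fit(data, network, order_policy, c, g, h, X_star, cs)
  meas_in_net <- network$pools$name %in%
    names(prep$data$measured)[prep$data$measured]
  if (!all(meas_in_net))
    stop("pool(s) ", paste(network$pools$name[!meas_in_net], collapse = ", "),
         " are unmeasured; use fit_with_hidden_pools()")
  run_fit(prep, hidden_x0 = NULL, config)
}

#' Fit with hidden (unmeasured) pools
#'
#' Extends [lm_fit()] to networks where some metabolites have no data:
#' the hidden pool's dimensionless rate constant A_h joins the parameter
#' vector (its steady state X_h* being unknown, A_h cannot be eliminated
#' through the constraints), the trajectories of all pools are still
#' integrated, but residuals are summed over measured pools only. The
#' hidden steady state is recovered afterwards from the flux-balance
#' composite: X_h* = Y_h / A_h.
#'
#' Parameter layout: free constants of measured pools, then composites
#' Y = X* A for hidden pools that are themselves in the free set, then
#' one A per hidden pool.
#'
#' @inheritParams lm_fit
#' @param hidden_x0 named dimensionless initial values for the hidden
#'   pools at the first data time (default 1; the choice matters and is
#'   reported, not silently optimized).
#' @return a `pendisc_fit`; `X_star_estimated` carries the recovered
#'   hidden steady states and `X_star` merges them (flagged via the
#'   `estimated` attribute).
#' @export
fit_with_hidden_pools <- function(data, network, order_policy = "fixed_half",
                                  c = 0.5, g = NULL, h = NULL, X_star = NULL,
                                  cs = NULL, config = fit_config(),
                                  hidden_x0 = NULL) {
  prep <- prepare_fit(data, network, order_policy, c, g, h, X_star, cs)
  run_fit(prep, hidden_x0, config)
}

prepare_fit <- function(data, network, order_policy, c, g, h, X_star, cs) {
  stopifnot(inherits(data, "pendisc_timeseries"))
  if (length(data$times) < 2) stop("need at least 2 time points")
  skel <- if (!is.null(g) || !is.null(h))
    build_ssystem(network, "given", g = g, h = h)
  else build_ssystem(network, order_policy, c = c)
  if (is.null(X_star) && !is.null(cs)) X_star <- cs$X_star
  if (is.null(X_star))
    stop("supply X_star (known or estimated via steady_states_from_data)")
  X_star <- expand_xstar(X_star, network$pools$name)
  meas <- names(data$measured)[data$measured]
  if (anyNA(X_star[intersect(meas, names(X_star))]))
    stop("X_star must be known for every measured pool")
  if (!data$dimensionless) data <- to_dimensionless(data, X_star)
  if (is.null(cs)) cs <- derive_constraints(network, X_star)
  list(data = data, network = network, skel = skel, cs = cs)
}

run_fit <- function(prep, hidden_x0, config) {
  obj <- make_objective(prep$network, prep$skel$g, prep$skel$h, prep$cs,
                        prep$data, hidden_x0,
                        config$ode_rtol, config$ode_atol)
  theta0 <- rep_len(config$initial_guess, obj$n_par)
  res <- lm_core(obj$residuals, theta0, config)
  ex <- obj$expand(res$theta)
  X_full <- prep$cs$X_star
  X_full[names(ex$X_star_est)] <- ex$X_star_est
  dm <- dimensionless_model(prep$network, ex$A, prep$skel$g, prep$skel$h,
                            X_full)
  ab <- redimensionalize(dm)
  free_A <- ex$A[intersect(prep$cs$free, names(ex$A))]
  mse_val <- obj$mse(res$theta)
  structure(list(
    free_A = free_A,
    theta = stats::setNames(res$theta, obj$par_names),
    full_A = ex$A,
    alpha = ab$alpha, beta = ab$beta,
    X_star = X_full,
    X_star_estimated = ex$X_star_est,
    hidden = obj$hidden,
    hidden_x0 = if (length(obj$hidden)) obj$x0[obj$hidden] else NULL,
    chi2 = res$chi2, chi2_trace = res$chi2_trace,
    iterations = res$iterations, converged = res$converged,
    criterion = res$criterion,
    mse = mse_val,
    model = dm, cs = prep$cs, config = config,
    data = prep$data),
    class = "pendisc_fit")
}

#' @export
print.pendisc_fit <- function(x, ...) {
  cat("pendisc fit:", if (x$converged) "converged" else "NOT converged",
      paste0("(", x$criterion, ")"), "after", x$iterations, "iterations\n")
  cat("  chi2 =", format(x$chi2), "  dimensionless MSE =", format(x$mse), "\n")
  cat("  free A:", paste0(names(x$free_A), " = ",
                          format(x$free_A, digits = 10), collapse = ", "), "\n")
  if (length(x$X_star_estimated))
    cat("  estimated hidden X*:",
        paste0(names(x$X_star_estimated), " = ",
               format(x$X_star_estimated, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Hidden-pool steady state from converged rate constants
#'
#' At a flux balance the composite Y_h = X_h* A_h of a hidden pool is an
#' affine function of the free constants; dividing by the fitted A_h
#' splits the composite and recovers the steady-state concentration. For
#' the branched benchmark arrangement (hidden pool fed by the branch
#' remainder) this is X_2* = (A_1 X_1* - A_4 X_4*) / A_2.
#'
#' @param cs constraint set (hidden pool may have `NA` steady state).
#' @param free_A named free constants of measured pools.
#' @param A_hidden named fitted constants of hidden pools.
#' @param free_Y named composites for hidden pools in the free set, if any.
#' @return named vector of estimated steady states for the hidden pools.
#' @examples
#' fx <- branched_reference()
#' Xs <- fx$X_star; Xs["X2"] <- NA
#' cs <- derive_constraints(fx$network, Xs)
#' estimate_hidden_steady_state(cs, free_A = c(X1 = 39.62943, X4 = 23.82671),
#'                              A_hidden = c(X2 = 4.38212))
#' @export
estimate_hidden_steady_state <- function(cs, free_A, A_hidden,
                                         free_Y = NULL) {
  stopifnot(inherits(cs, "pendisc_constraints"), all(A_hidden > 0))
  hidden <- names(A_hidden)
  freeY <- stats::setNames(numeric(length(cs$free)), cs$free)
  fm <- setdiff(cs$free, hidden)
  if (!all(fm %in% names(free_A)))
    stop("free_A must name every measured free pool: ",
         paste(fm, collapse = ", "))
  freeY[fm] <- cs$X_star[fm] * free_A[fm]
  fh <- intersect(cs$free, hidden)
  if (length(fh)) {
    if (is.null(free_Y) || !all(fh %in% names(free_Y)))
      stop("free_Y composites required for hidden free pool(s): ",
           paste(fh, collapse = ", "))
    freeY[fh] <- free_Y[fh]
  }
  Y <- expand_composites(freeY, cs)
  est <- Y[hidden] / A_hidden
  if (any(est <= 0))
    infeasible("non-positive hidden steady-state estimate")
  est
}
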