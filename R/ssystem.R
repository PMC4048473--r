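#' Build an S-system model skeleton from a pathway network
#'
#' In an S-system every pool's net influx and net efflux are each a single
#' product of power laws: dXi/dt = alpha_i prod_j Xj^g_ij - beta_i prod_j
#' Xj^h_ij. All influxes of a pool aggregate into the first term, all
#' effluxes into the second. This function derives the kinetic-order
#' matrices `g` and `h` from the network structure under an order policy;
#' the rate constants `alpha`/`beta` are left unset (to be supplied or
#' recovered from fitted dimensionless constants).
#'
#' The default policy fixes every order's magnitude at 0.5 — an average
#' of the exponents that power-law transformations of Michaelis-Menten
#' kinetics typically produce (mostly between 0 and 1) — with sign by
#' role: precursors and activators positive, inhibitors negative.
#'
#' @param network a [pathway_network()].
#' @param order_policy `"fixed_half"` (all magnitudes 0.5), `"uniform"`
#'   (all magnitudes `c`), or `"given"` (use the supplied matrices).
#' @param c order magnitude for `order_policy = "uniform"`.
#' @param g,h kinetic-order matrices for `order_policy = "given"`.
#' @param alpha,beta optional positive rate-constant vectors.
#' @return an object of class `pendisc_ssystem` with elements `network`,
#'   `alpha`, `beta`, `g`, `h`.
#' @examples
#' net <- branched_reference()$network
#' mod <- build_ssystem(net)          # orders +/-0.5
#' mod$g["X1", "X3"]                  # inhibition of the X1 influx: -0.5
#' @export
build_ssystem <- function(network,
                          order_policy = c("fixed_half", "uniform", "given"),
                          c = 0.5, g = NULL, h = NULL,
                          alpha = NULL, beta = NULL) {
  order_policy <- match.arg(order_policy)
  n <- network$n
  nm <- network$pools$name
  if (order_policy == "given") {
    stopifnot(!is.null(g), !is.null(h))
    g <- as.matrix(g); h <- as.matrix(h)
    stopifnot(all(dim(g) == n), all(dim(h) == n))
    dimnames(g) <- dimnames(h) <- list(nm, nm)
  } else {
    mag <- if (order_policy == "fixed_half") 0.5 else c
    g <- h <- matrix(0, n, n, dimnames = list(nm, nm))
    for (i in seq_len(n)) {
      for (f in influxes(network, nm[i])) {
        if (!identical(f$from, "EXTERNAL")) g[i, f$from] <- mag
        for (m in f$modifiers)
          g[i, m$pool] <- if (m$sign == "activation") mag else -mag
      }
      for (f in effluxes(network, nm[i])) {
        h[i, nm[i]] <- mag
        for (m in f$modifiers)
          h[i, m$pool] <- if (m$sign == "activation") mag else -mag
      }
    }
  }
  if (!is.null(alpha)) {
    stopifnot(length(alpha) == n, all(alpha > 0))
    alpha <- stats::setNames(as.numeric(alpha), nm)
  }
  if (!is.null(beta)) {
    stopifnot(length(beta) == n, all(beta > 0))
    beta <- stats::setNames(as.numeric(beta), nm)
  }
  structure(list(network = network, alpha = alpha, beta = beta, g = g, h = h),
            class = "pendisc_ssystem")
}

#' @export
print.pendisc_ssystem <- function(x, ...) {
  cat("S-system model,", x$network$n, "pools",
      if (is.null(x$alpha)) "(rate constants unset)" else "", "\n")
  nm <- x$network$pools$name
  for (i in seq_along(nm)) {
    term <- function(M, const) {
      j <- which(M[i, ] != 0)
      paste0(const, if (length(j)) paste0(" ", paste0(nm[j], "^", M[i, j],
                                                      collapse = " ")) else "")
    }
    a <- if (is.null(x$alpha)) paste0("alpha_", i) else format(x$alpha[i])
    b <- if (is.null(x$beta)) paste0("beta_", i) else format(x$beta[i])
    cat("  d", nm[i], "/dt = ", term(x$g, a), " - ", term(x$h, b), "\n", sep = "")
  }
  invisible(x)
}

# Right-hand side in concentration space. Positive clamp keeps the stiff
# integrator from evaluating log of a transient negative trial step.
ssystem_rhs <- function(model) {
  g <- model$g; h <- model$h
  la <- log(model$alpha); lb <- log(model$beta)
  function(t, X, parms) {
    y <- log(pmax(X, 1e-300))
    list(exp(la + as.vector(g %*% y)) - exp(lb + as.vector(h %*% y)))
  }
}

dimensionless_rhs <- function(model) {
  g <- model$g; h <- model$h; A <- model$A
  function(t, x, parms) {
    y <- log(pmax(x, 1e-300))
    list(A * (exp(as.vector(g %*% y)) - exp(as.vector(h %*% y))))
  }
}

#' Solve the steady state of an S-system model
#'
#' S-system steady-state conditions are linear in log-concentrations:
#' log(alpha_i) + sum_j g_ij y_j = log(beta_i) + sum_j h_ij y_j with
#' y = log X. When `g - h` is nonsingular the state is obtained by one
#' linear solve; otherwise a damped Newton iteration on the log-space
#' residual is used starting from `guess`.
#'
#' @param model a parameterized `pendisc_ssystem` (or a
#'   `pendisc_dimensionless`, whose steady state is all-ones by
#'   construction).
#' @param guess positive starting vector for the Newton fallback.
#' @param tol absolute residual tolerance on dX/dt at the solution.
#' @return named vector of steady-state concentrations.
#' @examples
#' fx <- branched_reference()
#' round(steady_state(fx$model), 4)   # 0.3996 2.0061 2.2284 0.1428
#' @export
steady_state <- function(model, guess = NULL, tol = 1e-12) {
  if (inherits(model, "pendisc_dimensionless"))
    return(stats::setNames(rep(1, model$network$n), model$network$pools$name))
  stopifnot(inherits(model, "pendisc_ssystem"),
            !is.null(model$alpha), !is.null(model$beta))
  n <- model$network$n
  M <- model$g - model$h
  b <- log(model$beta) - log(model$alpha)
  y <- NULL
  if (abs(det(M)) > 1e-12) {
    y <- solve(M, b)
  } else {
    # damped Newton on r(y) = exp(la + g y) - exp(lb + h y)
    y <- if (is.null(guess)) rep(0, n) else log(guess)
    la <- log(model$alpha); lb <- log(model$beta)
    for (it in 1:200) {
      vi <- exp(la + as.vector(model$g %*% y))
      vo <- exp(lb + as.vector(model$h %*% y))
      r <- vi - vo
      if (max(abs(r)) < tol) break
      J <- model$g * vi - model$h * vo
      step <- tryCatch(solve(J, r), error = function(e)
        stop("steady-state Newton iteration: singular Jacobian"))
      lam <- 1
      repeat {
        y2 <- y - lam * step
        r2 <- exp(la + as.vector(model$g %*% y2)) - exp(lb + as.vector(model$h %*% y2))
        if (all(is.finite(r2)) && max(abs(r2)) < max(abs(r)) || lam < 1e-8) break
        lam <- lam / 2
      }
      y <- y2
    }
  }
  X <- exp(y)
  res <- ssystem_rhs(model)(0, X, NULL)[[1]]
  if (max(abs(res)) > max(tol, 1e-9 * max(abs(model$alpha))))
    stop("steady-state solve did not converge (max residual ",
         format(max(abs(res))), ")")
  stats::setNames(X, model$network$pools$name)
}

#' Non-dimensionalize an S-system model around a steady state
#'
#' Concentrations are rescaled by their steady-state values, x = X/X*.
#' The influx constant becomes A_i = alpha_i/X_i* prod_j Xj*^g_ij and the
#' efflux constant B_i = beta_i/X_i* prod_j Xj*^h_ij; at a steady state
#' A_i = B_i, so the dimensionless model keeps a single vector A and reads
#' dx_i/dt = A_i (prod x^g_ij - prod x^h_ij), with all-ones steady state.
#' `B` is computed independently and checked against `A`: disagreement
#' means `X_star` is not a steady state of the model.
#'
#' @param model a fully parameterized `pendisc_ssystem`.
#' @param X_star positive steady-state vector (defaults to
#'   [steady_state()] of the model).
#' @param tol relative tolerance for the A = B flux-balance check.
#' @return an object of class `pendisc_dimensionless` with elements
#'   `network`, `A`, `g`, `h`, `X_star`.
#' @export
nondimensionalize <- function(model, X_star = NULL, tol = 1e-6) {
  stopifnot(inherits(model, "pendisc_ssystem"),
            !is.null(model$alpha), !is.null(model$beta))
  if (is.null(X_star)) X_star <- steady_state(model)
  stopifnot(all(X_star > 0), length(X_star) == model$network$n)
  y <- log(X_star)
  A <- model$alpha / X_star * exp(as.vector(model$g %*% y))
  B <- model$beta / X_star * exp(as.vector(model$h %*% y))
  if (max(abs(A - B) / pmax(A, B)) > tol)
    stop("influx and efflux dimensionless constants disagree (max rel ",
         format(max(abs(A - B) / pmax(A, B))),
         "): X_star is not a steady state of this model")
  dimensionless_model(model$network, A, model$g, model$h, X_star)
}

dimensionless_model <- function(network, A, g, h, X_star) {
  stopifnot(all(A > 0))
  structure(list(network = network,
                 A = stats::setNames(as.numeric(A), network$pools$name),
                 g = g, h = h,
                 X_star = stats::setNames(as.numeric(X_star), network$pools$name)),
            class = "pendisc_dimensionless")
}

#' @export
print.pendisc_dimensionless <- function(x, ...) {
  cat("dimensionless S-system model,", x$network$n, "pools\n")
  cat("  A      =", format(x$A, digits = 8), "\n")
  cat("  X_star =", format(x$X_star, digits = 6), "\n")
  invisible(x)
}

#' Recover dimensional rate constants from a dimensionless model
#'
#' Inverts the non-dimensionalization: alpha_i = A_i X_i* / prod_j
#' Xj*^g_ij and beta_i = A_i X_i* / prod_j Xj*^h_ij. Composed with
#' [nondimensionalize()] this is the identity to round-off.
#'
#' @param dimless a `pendisc_dimensionless` model.
#' @return list with positive vectors `alpha` and `beta`.
#' @export
redimensionalize <- function(dimless) {
  stopifnot(inherits(dimless, "pendisc_dimensionless"))
  y <- log(dimless$X_star)
  list(alpha = dimless$A * dimless$X_star / exp(as.vector(dimless$g %*% y)),
       beta  = dimless$A * dimless$X_star / exp(as.vector(dimless$h %*% y)))
}

#' Simulate model trajectories
#'
#' Integrates the S-system (or its dimensionless form) with a
#' stiff-capable solver (`deSolve::lsoda`). Default tolerances are tight
#' enough that generated fixtures are far more accurate than any fit
#' tolerance; fitting uses looser internal settings.
#'
#' @param model `pendisc_ssystem` or `pendisc_dimensionless`.
#' @param x0 positive state at `times[1]`.
#' @param times strictly increasing output times.
#' @param rtol,atol integrator tolerances.
#' @return a [timeseries()] object (dimensionless flag set from the model
#'   class).
#' @export
simulate_model <- function(model, x0, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(all(x0 > 0), all(diff(times) > 0) || length(times) == 1)
  rhs <- if (inherits(model, "pendisc_dimensionless")) dimensionless_rhs(model)
         else ssystem_rhs(model)
  out <- deSolve::lsoda(y = stats::setNames(as.numeric(x0), model$network$pools$name),
                        times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) stop("ODE integration failed")
  vals <- out[, -1, drop = FALSE]
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("trajectory left the positive orthant or blew up")
  timeseries(times = times, values = vals,
             dimensionless = inherits(model, "pendisc_dimensionless"))
}

#' Stiffness ratio of a vector field at a state
#'
#' Ratio of the maximum to the minimum absolute real part of the Jacobian
#' eigenvalues (real parts that are numerically zero are excluded and
#' reported). Large values indicate widely separated timescales, i.e.
#' stiffness. The Jacobian is computed with Richardson-extrapolated
#' central differences.
#'
#' @param rhs function `f(state) -> dstate/dt`, or a pendisc model object.
#' @param state evaluation point, typically the steady state (a warning is
#'   issued if the field is far from zero there).
#' @return list with `ratio`, `eigenvalues`, and `n_zero_real` (count of
#'   eigenvalues with numerically zero real part; `ratio` is `NA` if all
#'   real parts vanish).
#' @export
stiffness_ratio <- function(rhs, state) {
  if (inherits(rhs, "pendisc_ssystem")) {
    f0 <- ssystem_rhs(rhs); rhs <- function(x) f0(0, x, NULL)[[1]]
  } else if (inherits(rhs, "pendisc_dimensionless")) {
    f0 <- dimensionless_rhs(rhs); rhs <- function(x) f0(0, x, NULL)[[1]]
  }
  v <- rhs(state)
  if (max(abs(v)) > 1e-6 * max(1, max(abs(state))))
    warning("state is not close to an equilibrium; stiffness ratio is local")
  J <- num_jacobian(rhs, state)
  ev <- eigen(J, only.values = TRUE)$values
  re <- abs(Re(ev))
  zero_tol <- 1e-9 * max(re, 1)
  nz <- re[re > zero_tol]
  list(ratio = if (length(nz)) max(nz) / min(nz) else NA_real_,
       eigenvalues = ev,
       n_zero_real = sum(re <= zero_tol))
}
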