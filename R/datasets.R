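#' Branched benchmark model with inhibition and activation
#'
#' A four-pool branched pathway: an external source feeds X1 (inhibited
#' by X3), X1 branches into X2 and X4, X2 feeds X3, and X3 (efflux
#' activated by X4) and X4 drain externally. The fully parameterized
#' S-system is
#' \deqn{dX_1/dt = 12 X_3^{-0.8} - 10 X_1^{0.5}}
#' \deqn{dX_2/dt = 8 X_1^{0.5} - 3 X_2^{0.75}}
#' \deqn{dX_3/dt = 3 X_2^{0.75} - 5 X_3^{0.5} X_4^{0.2}}
#' \deqn{dX_4/dt = 2 X_1^{0.5} - 6 X_4^{0.8}}
#' with initial state X0 = (1.4, 2.7, 1.2, 0.4) and steady state
#' (0.39956, 2.00607, 2.22837, 0.14275). Its dimensionless rate
#' constants are A = (15.820082, 2.520778, 2.269310, 8.855921), with
#' the branch balance X1* A1 = X2* A2 + X4* A4 and chain balance
#' X2* A2 = X3* A3 holding exactly. The fixture self-checks these
#' identities at construction.
#'
#' @return object of class `pendisc_fixture`: `network`, `model`, `X0`,
#'   `X_star`, `A_true`, `notes`.
#' @export
branched_reference <- function() {
  net <- pathway_network(
    c("X1", "X2", "X3", "X4"),
    list(flux("EXTERNAL", "X1", modifiers = list(list(pool = "X3", sign = "inhibition"))),
         flux("X1", "X2"),
         flux("X1", "X4"),
         flux("X2", "X3"),
         flux("X3", "EXTERNAL", modifiers = list(list(pool = "X4", sign = "activation"))),
         flux("X4", "EXTERNAL")))
  nm <- net$pools$name
  g <- h <- matrix(0, 4, 4, dimnames = list(nm, nm))
  g["X1", "X3"] <- -0.8
  g["X2", "X1"] <- 0.5
  g["X3", "X2"] <- 0.75
  g["X4", "X1"] <- 0.5
  h["X1", "X1"] <- 0.5
  h["X2", "X2"] <- 0.75
  h["X3", "X3"] <- 0.5
  h["X3", "X4"] <- 0.2
  h["X4", "X4"] <- 0.8
  model <- build_ssystem(net, "given", g = g, h = h,
                         alpha = c(12, 8, 3, 2), beta = c(10, 3, 5, 6))
  X0 <- stats::setNames(c(1.4, 2.7, 1.2, 0.4), nm)
  fixture(net, model, X0,
          notes = "branched 4-pool benchmark; synthetic reference system")
}

#' Linear-chain benchmark model
#'
#' A chain of n pools with constant external input to the first:
#' dX1/dt = alpha1 - beta1 X1^h11, dXi/dt = beta_{i-1} X_{i-1}^{h_{i-1}}
#' - beta_i Xi^{h_i}. The structural constraints reduce it to a single
#' free dimensionless constant, with X1* A1 = Xi* Ai for every i.
#'
#' @param n number of pools (>= 2).
#' @param alpha1 input rate constant.
#' @param betas efflux rate constants, length n.
#' @param orders efflux kinetic orders h_ii, length n (recycled).
#' @param X0 initial state; default 1.5 times the steady state.
#' @return a `pendisc_fixture`.
#' @export
linear_chain <- function(n, alpha1 = 1, betas = rep(1, n),
                         orders = rep(0.5, n), X0 = NULL) {
  stopifnot(n >= 2, alpha1 > 0, all(betas > 0), all(orders > 0))
  betas <- rep_len(betas, n); orders <- rep_len(orders, n)
  nm <- paste0("X", seq_len(n))
  fl <- c(list(flux("EXTERNAL", nm[1])),
          lapply(seq_len(n - 1), function(i) flux(nm[i], nm[i + 1])),
          list(flux(nm[n], "EXTERNAL")))
  net <- pathway_network(nm, fl)
  g <- h <- matrix(0, n, n, dimnames = list(nm, nm))
  alpha <- numeric(n)
  alpha[1] <- alpha1
  for (i in seq_len(n)) h[i, i] <- orders[i]
  for (i in 2:n) {
    g[i, i - 1] <- orders[i - 1]
    alpha[i] <- betas[i - 1]
  }
  model <- build_ssystem(net, "given", g = g, h = h,
                         alpha = alpha, beta = betas)
  Xs <- steady_state(model)
  if (is.null(X0)) X0 <- 1.5 * Xs
  fixture(net, model, X0, X_star = Xs,
          notes = paste0("linear chain benchmark, n = ", n))
}

#' Aspartate-derived amino acid biosynthesis topology
#'
#' Seven-pool flux topology of the plant aspartate pathway:
#' l-aspartyl-4-phosphate (X1) -> l-aspartate-semialdehyde (X2), which
#' branches to l-lysine (X3) and l-homoserine (X4); then
#' X4 -> O-phospho-l-homoserine (X5) -> l-threonine (X6) ->
#' l-isoleucine (X7); external input to X1, external sinks from X3 and
#' X7. With its single branch point the structural constraints reduce
#' the seven dimensionless rate constants to two.
#'
#' This is a topology-only fixture (no rate law is attached): constraint
#' counting and reduction are independent of the kinetics. Optional
#' feedback modifiers (end-product inhibition by lysine, threonine and
#' isoleucine) can be attached; they alter kinetic orders only, never
#' the constraints.
#'
#' @param regulation include the feedback-inhibition modifier edges.
#' @return a `pendisc_fixture` with `model = NULL`.
#' @export
aspartate_network <- function(regulation = FALSE) {
  nm <- paste0("X", 1:7)
  long <- c("l-aspartyl-4-phosphate", "l-aspartate-semialdehyde",
            "l-lysine", "l-homoserine", "O-phospho-l-homoserine",
            "l-threonine", "l-isoleucine")
  mods <- function(...) if (regulation) list(...) else list()
  fl <- list(
    flux("EXTERNAL", "X1",
         modifiers = mods(list(pool = "X3", sign = "inhibition"),
                          list(pool = "X6", sign = "inhibition"))),
    flux("X1", "X2"),
    flux("X2", "X3", modifiers = mods(list(pool = "X3", sign = "inhibition"))),
    flux("X2", "X4", modifiers = mods(list(pool = "X6", sign = "inhibition"))),
    flux("X4", "X5"),
    flux("X5", "X6"),
    flux("X6", "X7", modifiers = mods(list(pool = "X7", sign = "inhibition"))),
    flux("X3", "EXTERNAL"),
    flux("X7", "EXTERNAL"))
  net <- pathway_network(nm, fl)
  structure(list(network = net, model = NULL, X0 = NULL, X_star = NULL,
                 A_true = NULL,
                 notes = paste("aspartate pathway topology;",
                               paste(nm, long, sep = " = ", collapse = "; "))),
            class = "pendisc_fixture")
}

fixture <- function(network, model, X0, X_star = NULL, notes = "") {
  if (is.null(X_star)) X_star <- steady_state(model)
  # fail fast: stored steady state must solve the model, and the model
  # must relax back to it from X0
  chk <- steady_state(model)
  stopifnot(max(abs(chk - X_star) / X_star) < 1e-6)
  A_true <- nondimensionalize(model, X_star)$A
  structure(list(network = network, model = model, X0 = X0,
                 X_star = X_star, A_true = A_true, notes = notes),
            class = "pendisc_fixture")
}

#' @export
print.pendisc_fixture <- function(x, ...) {
  cat("pendisc fixture:", x$notes, "\n")
  print(x$network)
  if (!is.null(x$X_star))
    cat("  X* =", format(x$X_star, digits = 6), "\n")
  invisible(x)
}

#' Generate synthetic time-series data from a fixture
#'
#' Integrates the fixture model from its initial state on an equally
#' spaced grid, optionally multiplies each point by (1 + u) with u
#' uniform on \[-noise_level, +noise_level\], and drops hidden pools.
#' Integration tolerances (1e-10/1e-12) are far tighter than any fit
#' tolerance, so the noise-free data are exact for practical purposes.
#'
#' @param fx a `pendisc_fixture` with a parameterized model.
#' @param n_points number of time points (>= 2); 11 and 21 are the
#'   benchmark sizes.
#' @param t_end end of the grid `[0, t_end]`; default 5, which places an
#'   early interior point at t = 0.5 on the 11-point grid.
#' @param noise_level relative noise bound in `[0, 1)`.
#' @param seed RNG seed for the noise (recorded in the provenance).
#' @param hidden pool names to mark unmeasured (columns set `NA`).
#' @return a dimensional [timeseries()] with attribute `provenance`.
#' @export
generate_timeseries <- function(fx, n_points = 11, t_end = 5,
                                noise_level = 0, seed = NULL,
                                hidden = character(0)) {
  stopifnot(inherits(fx, "pendisc_fixture"), !is.null(fx$model),
            n_points >= 2)
  times <- seq(0, t_end, length.out = n_points)
  ts <- simulate_model(fx$model, fx$X0, times)
  if (noise_level > 0)
    ts <- add_noise(ts, noise_level, seed = seed)
  if (length(hidden)) {
    stopifnot(all(hidden %in% colnames(ts$values)))
    ts$values[, hidden] <- NA_real_
    ts$measured[hidden] <- FALSE
  }
  attr(ts, "provenance") <- list(n_points = n_points, t_end = t_end,
                                 noise_level = noise_level, seed = seed,
                                 hidden = hidden)
  ts
}
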