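# Shared fixtures and independent oracles for the test suite.

# Printed reference values for the branched benchmark (rounded steady
# states as reported; full-precision values come from the solver itself).
branched_Xstar_4dp <- c(X1 = 0.3996, X2 = 2.0061, X3 = 2.2284, X4 = 0.1428)
branched_A_ref <- c(X1 = 15.82007531, X2 = 2.52077734,
                    X3 = 2.26931039, X4 = 8.85591652)

# brute-force product evaluation of one power-law term (independent of
# the package's log-space vectorized route)
brute_term <- function(const, X, orders) {
  out <- const
  for (j in seq_along(X)) out <- out * X[j]^orders[j]
  out
}

brute_rhs <- function(model, X) {
  n <- length(X)
  vapply(seq_len(n), function(i)
    brute_term(model$alpha[i], X, model$g[i, ]) -
      brute_term(model$beta[i], X, model$h[i, ]), numeric(1))
}

# loop-based chi-square oracle: straight transcription of the weighted
# sum over measured pools and time points
brute_chi2 <- function(data_vals, pred_vals, sigma, measured) {
  s <- 0
  for (p in measured)
    for (k in seq_len(nrow(data_vals)))
      s <- s + ((data_vals[k, p] - pred_vals[k, p]) / sigma[k, p])^2
  unname(s)
}

# random linear chain with positive parameters, reproducible via seed
random_chain <- function(n, seed) {
  set.seed(seed)
  linear_chain(n, alpha1 = runif(1, 0.5, 3),
               betas = runif(n, 0.5, 3),
               orders = runif(n, 0.3, 0.9))
}

# random branched tree network (single external source, tree effluxes,
# external sinks at every leaf) with per-pool random kinetic parameters
random_tree_fixture <- function(n, seed, n_branch = 1) {
  set.seed(seed)
  nm <- paste0("X", seq_len(n))
  fl <- list(flux("EXTERNAL", nm[1]))
  children <- vector("list", n)
  parent <- rep(NA_integer_, n)
  branch_at <- sample(seq_len(max(1, n - 2)), n_branch)
  nxt <- 2
  for (i in seq_len(n)) {
    if (nxt > n) break
    kids <- if (i %in% branch_at) min(2, n - nxt + 1) else 1
    for (k in seq_len(kids)) {
      if (nxt > n) break
      fl <- c(fl, list(flux(nm[i], nm[nxt])))
      parent[nxt] <- i
      children[[i]] <- c(children[[i]], nxt)
      nxt <- nxt + 1
    }
  }
  for (i in seq_len(n))
    if (is.null(children[[i]])) fl <- c(fl, list(flux(nm[i], "EXTERNAL")))
  net <- pathway_network(nm, fl)
  g <- h <- matrix(0, n, n, dimnames = list(nm, nm))
  alpha <- beta <- numeric(n)
  ords <- runif(n, 0.3, 0.9)
  for (i in seq_len(n)) {
    h[i, i] <- ords[i]
    if (is.na(parent[i])) {
      alpha[i] <- runif(1, 1, 4)
    } else {
      g[i, parent[i]] <- ords[parent[i]]
      alpha[i] <- runif(1, 0.5, 2)
    }
    beta[i] <- runif(1, 1, 4)
  }
  # make flux balance hold at branch points: children influx constants
  # must sum to the parent efflux constant (shared order => shared term)
  for (i in seq_len(n)) {
    kids <- children[[i]]
    if (length(kids) >= 2) {
      w <- runif(length(kids)); w <- w / sum(w)
      alpha[kids] <- beta[i] * w
    } else if (length(kids) == 1) alpha[kids] <- beta[i]
  }
  model <- build_ssystem(net, "given", g = g, h = h, alpha = alpha, beta = beta)
  Xs <- steady_state(model)
  fx <- list(network = net, model = model, X_star = Xs,
             X0 = Xs * runif(n, 0.6, 1.8), A_true = nondimensionalize(model, Xs)$A)
  class(fx) <- "pendisc_fixture"
  fx
}
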