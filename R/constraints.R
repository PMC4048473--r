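#' Derive rate-constant constraints from the network structure
#'
#' At a steady state the product Y_i = X_i* A_i equals the total flux
#' through pool i. Interpreting the aggregated S-system terms as sums of
#' the underlying edge fluxes yields affine relations among the Y_i:
#'
#' * a chain edge i -> j (j's only influx) gives Y_i = Y_j;
#' * a branch point b feeding children c_1..c_q gives
#'   Y_b = Y_c1 + ... + Y_cq;
#' * a confluence of u_1..u_q into pool p gives Y_u1 + ... + Y_uq = Y_p.
#'
#' The relations reduce the n dimensionless rate constants to a small
#' free set: one for the pathway plus one per branch point (for tree-like
#' single-source topologies; extra external sources each add one more).
#' The free set is chosen deterministically: the first pool in
#' topological order, plus the highest-index internal child of each
#' branch point. Every other A_i is an explicit linear function of the
#' free ones with coefficients built from X*.
#'
#' Hidden pools may carry `NA` in `X_star`: relations are derived at the
#' Y level regardless, and the composite Y_i = X_i* A_i is only split
#' into its factors at reporting time.
#'
#' @param network a [pathway_network()].
#' @param X_star named steady-state vector; `NA` entries allowed for
#'   hidden pools.
#' @return object of class `pendisc_constraints` with elements
#'   `relations` (human-readable records), `R` (relation matrix over Y),
#'   `free` (free pool names), `expansion` (matrix E with Y = E Y_free),
#'   `X_star`, `network`.
#' @examples
#' fx <- branched_reference()
#' cs <- derive_constraints(fx$network, fx$X_star)
#' cs$free                                   # "X1" "X4"
#' expand_rate_constants(c(X1 = 15.82, X4 = 8.856), cs)
#' @export
derive_constraints <- function(network, X_star) {
  nm <- network$pools$name
  n <- network$n
  X_star <- expand_xstar(X_star, nm)

  rel <- list()
  add_rel <- function(lhs, rhs, type) {
    rel[[length(rel) + 1L]] <<- list(type = type, lhs = lhs, rhs = rhs)
  }
  # efflux side: pool i whose effluxes are all internal, each child fed
  # only by i -> Y_i = sum of children Y (chain when one child)
  for (p in nm) {
    eff <- effluxes(network, p)
    tgt <- vapply(eff, `[[`, "", "to")
    if (any(tgt == "EXTERNAL")) next
    kids <- unique(tgt)
    ok <- all(vapply(kids, function(k) {
      src <- vapply(influxes(network, k), `[[`, "", "from")
      all(src == p)
    }, TRUE))
    if (ok) add_rel(p, kids, if (length(kids) >= 2) "branch" else "chain")
  }
  # influx side: confluence of >= 2 pools, each feeding only this pool
  for (p in nm) {
    inf <- influxes(network, p)
    src <- vapply(inf, `[[`, "", "from")
    if (any(src == "EXTERNAL")) next
    ups <- unique(src)
    if (length(ups) < 2) next
    ok <- all(vapply(ups, function(u) {
      tg <- vapply(effluxes(network, u), `[[`, "", "to")
      all(tg == p)
    }, TRUE))
    if (ok) add_rel(ups, p, "confluence")
  }

  R <- matrix(0, length(rel), n, dimnames = list(NULL, nm))
  for (k in seq_along(rel)) {
    R[k, rel[[k]]$lhs] <- 1
    R[k, rel[[k]]$rhs] <- R[k, rel[[k]]$rhs] - 1
  }
  rnk <- if (nrow(R)) qr(R)$rank else 0L
  n_free <- n - rnk

  # deterministic free-set preference: first pool of the topological
  # order, then the highest-index internal child of each branch point,
  # then everything else in topological order
  topo <- topological_order(network)
  pref <- topo[1]
  for (b in branch_points(network)) {
    kids <- unique(vapply(Filter(function(f) !identical(f$to, "EXTERNAL"),
                                 effluxes(network, b)), `[[`, "", "to"))
    pref <- c(pref, kids[which.max(match(kids, nm))])
  }
  pref <- unique(c(pref, topo))

  # a pool may go free iff the remaining columns still span the full
  # relation rank (the dependent block stays uniquely solvable)
  free <- character(0)
  for (cand in pref) {
    if (length(free) == n_free) break
    trial <- c(free, cand)
    dep <- setdiff(nm, trial)
    if (rnk == 0L ||
        qr(R[, dep, drop = FALSE])$rank == rnk)
      free <- trial
  }
  if (length(free) != n_free)
    stop("no valid elimination order for this flux topology ",
         "(cyclic structure without external input?)")

  dep <- setdiff(nm, free)
  E <- matrix(0, n, n_free, dimnames = list(nm, free))
  E[free, free] <- diag(n_free)
  if (length(dep)) {
    # R_dep Y_dep = -R_free Y_free
    Rd <- R[, dep, drop = FALSE]
    Rf <- R[, free, drop = FALSE]
    sol <- qr.solve(Rd, -Rf)
    E[dep, ] <- sol
  }
  structure(list(relations = rel, R = R, free = free, expansion = E,
                 X_star = X_star, network = network),
            class = "pendisc_constraints")
}

expand_xstar <- function(X_star, nm) {
  if (is.null(names(X_star))) {
    stopifnot(length(X_star) == length(nm))
    names(X_star) <- nm
  }
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  out[names(X_star)] <- X_star
  if (any(!is.na(out) & out <= 0)) stop("X_star entries must be positive")
  out
}

#' @export
print.pendisc_constraints <- function(x, ...) {
  cat("constraint set:", length(x$relations), "relations, free constants:",
      paste0("A[", x$free, "]", collapse = ", "), "\n")
  for (r in x$relations)
    cat("  ", paste0("Y[", r$lhs, "]", collapse = " + "), "=",
        paste0("Y[", r$rhs, "]", collapse = " + "),
        paste0("(", r$type, ")\n"))
  invisible(x)
}

#' Expand free rate constants to the full vector
#'
#' Maps the free dimensionless rate constants through the constraint set:
#' Y_free = X*_free A_free, Y = E Y_free, A_i = Y_i / X_i*. A derived
#' A_i <= 0 (e.g. when the branch subtraction X_b* A_b - X_c* A_c goes
#' non-positive) raises a condition of class `pendisc_infeasible`, which
#' the optimizer treats as a rejected step; values are never clamped.
#'
#' @param free_values positive vector of free constants, in the order of
#'   `cs$free` (names checked when present).
#' @param cs a `pendisc_constraints` object with full (no-`NA`) `X_star`.
#' @return named full vector A satisfying every relation.
#' @export
expand_rate_constants <- function(free_values, cs) {
  stopifnot(inherits(cs, "pendisc_constraints"))
  if (anyNA(cs$X_star))
    stop("X_star has unknown entries; use the composite-Y interface ",
         "(fit_with_hidden_pools) for hidden pools")
  fv <- check_free(free_values, cs)
  Y <- as.vector(cs$expansion %*% (cs$X_star[cs$free] * fv))
  A <- stats::setNames(Y / cs$X_star, names(cs$X_star))
  if (any(A <= 0))
    infeasible("expanded rate constant(s) non-positive: ",
               paste(names(A)[A <= 0], collapse = ", "))
  A
}

check_free <- function(free_values, cs) {
  if (!is.null(names(free_values))) {
    if (!setequal(names(free_values), cs$free))
      stop("free_values names must be ", paste(cs$free, collapse = ", "))
    free_values <- free_values[cs$free]
  }
  stopifnot(length(free_values) == length(cs$free))
  if (any(free_values <= 0)) infeasible("free rate constants must be positive")
  free_values
}

# expansion at the composite level: Y = X* A (hidden pools stay composite)
expand_composites <- function(free_Y, cs) {
  stopifnot(length(free_Y) == length(cs$free))
  if (any(free_Y <= 0)) infeasible("free composites must be positive")
  Y <- as.vector(cs$expansion %*% free_Y)
  names(Y) <- rownames(cs$expansion)
  if (any(Y <= 0))
    infeasible("derived composite(s) non-positive: ",
               paste(names(Y)[Y <= 0], collapse = ", "))
  Y
}

infeasible <- function(...) {
  stop(structure(class = c("pendisc_infeasible", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Residual of the constraint relations
#'
#' Maximum absolute residual of every stored relation evaluated at a full
#' rate-constant vector, relative to the flux scale. Used by tests and by
#' fit post-conditions; exactly zero (to round-off) for any expanded
#' vector.
#'
#' @param cs a `pendisc_constraints`.
#' @param A full rate-constant vector.
#' @return scalar residual.
#' @export
constraint_residual <- function(cs, A) {
  if (!nrow(cs$R)) return(0)
  Y <- cs$X_star * A
  max(abs(cs$R %*% Y)) / max(abs(Y))
}

#' Count free parameters of a constrained network
#'
#' Number of dimensionless rate constants that remain free after applying
#' the structural constraints: the rank deficiency of the relation
#' system. For a single-source tree-like pathway with p branch points
#' this equals p + 1; a linear chain gives 1.
#'
#' @param network a [pathway_network()].
#' @return integer count.
#' @export
count_free_parameters <- function(network) {
  cs <- derive_constraints(network,
                           stats::setNames(rep(1, network$n),
                                           network$pools$name))
  length(cs$free)
}

#' Unknown-parameter count at each modeling stage
#'
#' For an S-system of N equations: the full model has 2N(N+1) unknowns
#' (2N rate constants, 2N^2 kinetic orders); fixing the orders leaves 2N;
#' non-dimensionalization halves that to N; structural constraints with p
#' branch points leave p + 1.
#'
#' @param N number of pools (>= 1).
#' @param stage one of `"full_ssystem"`, `"fixed_orders"`,
#'   `"dimensionless"`, `"constrained"`.
#' @param p branch-point count (stage `"constrained"` only).
#' @return integer.
#' @examples
#' parameter_count(4, "full_ssystem")   # 40
#' parameter_count(7, "constrained", p = 1)   # 2
#' @export
parameter_count <- function(N, stage = c("full_ssystem", "fixed_orders",
                                         "dimensionless", "constrained"),
                            p = 0) {
  stopifnot(N >= 1)
  switch(match.arg(stage),
         full_ssystem = 2 * N * (N + 1),
         fixed_orders = 2 * N,
         dimensionless = N,
         constrained = p + 1)
}
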