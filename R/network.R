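#' Define a metabolic flux
#'
#' A flux is a single enzymatic conversion step: material leaves `from` and
#' enters `to`. Either end may be the literal `"EXTERNAL"` for pathway
#' sources and sinks. Regulatory interactions acting on the flux are given
#' as modifiers with a sign: `"activation"` contributes a positive kinetic
#' order to the corresponding power-law term, `"inhibition"` a negative one.
#'
#' @param from name of the origin pool, or `"EXTERNAL"`.
#' @param to name of the target pool, or `"EXTERNAL"`.
#' @param id optional flux identifier; autogenerated as `"from->to"` if missing.
#' @param modifiers a list of `list(pool =, sign =)` entries, or a data frame
#'   with columns `pool` and `sign`; sign must be `"activation"` or
#'   `"inhibition"`. At most one entry per pool.
#' @return an object of class `pendisc_flux`.
#' @export
flux <- function(from, to, id = NULL, modifiers = list()) {
  if (identical(from, to))
    stop("flux origin and target must differ (got '", from, "' twice)")
  if (is.data.frame(modifiers))
    modifiers <- lapply(seq_len(nrow(modifiers)), function(i)
      list(pool = modifiers$pool[i], sign = modifiers$sign[i]))
  for (m in modifiers) {
    if (!all(c("pool", "sign") %in% names(m)))
      stop("each modifier needs 'pool' and 'sign'")
    if (!m$sign %in% c("activation", "inhibition"))
      stop("modifier sign must be 'activation' or 'inhibition', got '", m$sign, "'")
  }
  mp <- vapply(modifiers, `[[`, "", "pool")
  if (anyDuplicated(mp))
    stop("at most one modifier entry per pool per flux")
  if (is.null(id)) id <- paste0(from, "->", to)
  structure(list(id = id, from = from, to = to, modifiers = modifiers),
            class = "pendisc_flux")
}

#' Construct a pathway network
#'
#' The structural object from which both the S-system equations and the
#' rate-constant constraints are derived. Pools are metabolite
#' concentrations; fluxes connect them (or the `EXTERNAL` environment).
#' Every pool must have at least one influx and one efflux, because the
#' steady-state assumption underlying the non-dimensionalization requires
#' both power-law terms to be present and balanced.
#'
#' @param pools character vector of unique pool names (1-based indexing is
#'   positional), or a data frame with columns `name` and optionally
#'   `measured` (logical) and `steady_state` (numeric, `NA` = unknown).
#' @param fluxes a list of [flux()] objects.
#' @param measured logical vector (recycled) marking pools with data;
#'   ignored when `pools` is a data frame carrying its own column.
#' @return an object of class `pendisc_network` with elements `pools`
#'   (data frame: name, measured, steady_state), `fluxes`, and `n`.
#' @examples
#' net <- pathway_network(
#'   c("X1", "X2"),
#'   list(flux("EXTERNAL", "X1"), flux("X1", "X2"), flux("X2", "EXTERNAL")))
#' net
#' @export
pathway_network <- function(pools, fluxes, measured = TRUE) {
  if (is.data.frame(pools)) {
    pdf <- pools
    if (is.null(pdf$measured)) pdf$measured <- TRUE
    if (is.null(pdf$steady_state)) pdf$steady_state <- NA_real_
  } else {
    pdf <- data.frame(name = as.character(pools),
                      measured = rep_len(measured, length(pools)),
                      steady_state = NA_real_,
                      stringsAsFactors = FALSE)
  }
  if (nrow(pdf) < 1L) stop("network needs at least one pool")
  if (anyDuplicated(pdf$name)) stop("pool names must be unique")
  fluxes <- lapply(fluxes, function(f) {
    if (!inherits(f, "pendisc_flux")) f <- do.call(flux, f)
    f
  })
  net <- structure(list(pools = pdf, fluxes = fluxes, n = nrow(pdf)),
                   class = "pendisc_network")
  validate_network(net)
  net
}

#' @export
print.pendisc_network <- function(x, ...) {
  cat("pendisc pathway network:", x$n, "pools,", length(x$fluxes), "fluxes\n")
  cat("  pools:", paste(x$pools$name, collapse = ", "), "\n")
  for (f in x$fluxes) {
    mods <- if (length(f$modifiers))
      paste0(" [", paste(vapply(f$modifiers, function(m)
        paste0(substr(m$sign, 1, 3), ":", m$pool), ""), collapse = ", "), "]")
    else ""
    cat("  ", f$from, "->", f$to, mods, "\n")
  }
  bp <- branch_points(x)
  if (length(bp)) cat("  branch points:", paste(bp, collapse = ", "), "\n")
  invisible(x)
}

validate_network <- function(net) {
  nm <- net$pools$name
  for (f in net$fluxes) {
    for (end in c(f$from, f$to))
      if (!identical(end, "EXTERNAL") && !end %in% nm)
        stop("flux '", f$id, "' references unknown pool '", end, "'")
    for (m in f$modifiers)
      if (!m$pool %in% nm)
        stop("modifier on flux '", f$id, "' references unknown pool '", m$pool, "'")
  }
  for (p in nm) {
    if (!length(influxes(net, p)))
      stop("pool '", p, "' has no influx; the steady-state assumption needs both terms")
    if (!length(effluxes(net, p)))
      stop("pool '", p, "' has no efflux; the steady-state assumption needs both terms")
  }
  # weak connectivity over the flux graph (EXTERNAL treated as one node)
  if (net$n > 1L) {
    nodes <- c(nm, "EXTERNAL")
    adj <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    for (f in net$fluxes) adj[f$from, f$to] <- adj[f$to, f$from] <- TRUE
    seen <- c(nm[1])
    repeat {
      nxt <- nodes[apply(adj[seen, , drop = FALSE], 2, any)]
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
    }
    if (!all(nm %in% seen)) stop("flux graph is not connected")
  }
  invisible(net)
}

pool_index <- function(net, name) {
  i <- match(name, net$pools$name)
  if (anyNA(i)) stop("unknown pool(s): ", paste(name[is.na(i)], collapse = ", "))
  i
}

influxes <- function(net, pool)
  Filter(function(f) identical(f$to, pool), net$fluxes)

effluxes <- function(net, pool)
  Filter(function(f) identical(f$from, pool), net$fluxes)

#' Branch points of a network
#'
#' A branch point is a pool whose efflux splits into two or more fluxes
#' toward internal pools. Each branch point contributes one extra free
#' dimensionless rate constant to the constrained parameterization.
#'
#' @param net a [pathway_network()].
#' @return character vector of branch-point pool names (possibly empty).
#' @export
branch_points <- function(net) {
  Filter(function(p) {
    eff <- effluxes(net, p)
    sum(vapply(eff, function(f) !identical(f$to, "EXTERNAL"), TRUE)) >= 2L
  }, net$pools$name)
}

# Topological order of pools along internal fluxes; pools in cycles are
# appended in index order (the constraint solver rejects closed cycles
# itself when elimination fails).
topological_order <- function(net) {
  nm <- net$pools$name
  indeg <- vapply(nm, function(p)
    sum(vapply(influxes(net, p), function(f) !identical(f$from, "EXTERNAL"), TRUE)),
    0L)
  order_out <- character(0)
  avail <- nm[indeg == 0L]
  indeg2 <- indeg
  while (length(avail)) {
    p <- avail[[1]]; avail <- avail[-1]
    order_out <- c(order_out, p)
    for (f in effluxes(net, p)) if (!identical(f$to, "EXTERNAL")) {
      indeg2[f$to] <- indeg2[f$to] - 1L
      if (indeg2[f$to] == 0L) avail <- c(avail, f$to)
    }
  }
  c(order_out, setdiff(nm, order_out))
}
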