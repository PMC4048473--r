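#' Read a pathway network from a JSON spec file
#'
#' Schema: `{"pools": [{"name": "X1", "measured": true}, ...],
#' "fluxes": [{"id": "v1", "from": "X1"|"EXTERNAL", "to": ...,
#' "modifiers": [{"pool": "X3", "sign": "inhibition"}]}]}`. `measured`
#' defaults to true and `modifiers` to none. Validation errors name the
#' offending pool or flux.
#'
#' @param path JSON file path.
#' @return a [pathway_network()].
#' @export
load_network_spec <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$pools) || !length(doc$pools))
    stop("network spec '", path, "': empty or missing 'pools'")
  if (is.null(doc$fluxes) || !length(doc$fluxes))
    stop("network spec '", path, "': empty or missing 'fluxes'")
  pools <- data.frame(
    name = vapply(doc$pools, function(p) {
      if (is.null(p$name)) stop("network spec: pool without a name")
      p$name
    }, ""),
    measured = vapply(doc$pools, function(p)
      if (is.null(p$measured)) TRUE else isTRUE(p$measured), TRUE),
    stringsAsFactors = FALSE)
  fluxes <- lapply(doc$fluxes, function(f) {
    if (is.null(f$from) || is.null(f$to))
      stop("network spec: flux ", if (!is.null(f$id)) paste0("'", f$id, "' "),
           "needs 'from' and 'to'")
    mods <- lapply(f$modifiers, function(m) list(pool = m$pool, sign = m$sign))
    flux(f$from, f$to, id = f$id, modifiers = mods)
  })
  pathway_network(pools, fluxes)
}

#' Write a pathway network to a JSON spec file
#'
#' @param network a [pathway_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_spec <- function(network, path) {
  doc <- list(
    pools = lapply(seq_len(network$n), function(i)
      list(name = network$pools$name[i],
           measured = network$pools$measured[i])),
    fluxes = lapply(network$fluxes, function(f)
      list(id = f$id, from = f$from, to = f$to, modifiers = f$modifiers)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read time-series data from CSV
#'
#' Wide format: first column `time` (strictly increasing), one column
#' per pool, named as in the network. A pool with no column is marked
#' unmeasured — column absence is the explicit signal for a hidden
#' metabolite. An optional sigma CSV of identical layout supplies
#' per-point standard deviations.
#'
#' @param path CSV path.
#' @param network optional [pathway_network()]; when given, columns are
#'   checked against the pool names and missing pools added as
#'   unmeasured.
#' @param sigma_path optional sigma CSV.
#' @return a [timeseries()].
#' @export
load_timeseries <- function(path, network = NULL, sigma_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df) || names(df)[1] != "time")
    stop("'", path, "': first column must be 'time'")
  times <- df$time
  if (!is.numeric(times) || any(!is.finite(times)))
    stop("'", path, "': non-numeric time column")
  if (any(diff(times) <= 0))
    stop("'", path, "': time column must be strictly increasing")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("'", path, "': non-numeric concentration values")
  if (!is.null(network)) {
    unknown <- setdiff(colnames(vals), network$pools$name)
    if (length(unknown))
      stop("'", path, "': column(s) not in the network: ",
           paste(unknown, collapse = ", "))
    missing <- setdiff(network$pools$name, colnames(vals))
    if (length(missing)) {
      vals <- cbind(vals, matrix(NA_real_, nrow(vals), length(missing),
                                 dimnames = list(NULL, missing)))
    }
    vals <- vals[, network$pools$name, drop = FALSE]
  }
  sigma <- NULL
  if (!is.null(sigma_path)) {
    sdf <- utils::read.csv(sigma_path, check.names = FALSE)
    sigma <- matrix(1, nrow(vals), ncol(vals), dimnames = dimnames(vals))
    for (p in intersect(colnames(vals), names(sdf)))
      sigma[, p] <- sdf[[p]]
  }
  timeseries(times, vals, sigma = sigma)
}

#' Write a time series to CSV
#'
#' @param ts a [timeseries()].
#' @param path output path; unmeasured pools are omitted (column
#'   absence marks them).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  meas <- names(ts$measured)[ts$measured]
  df <- data.frame(time = ts$times, ts$values[, meas, drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write fit results (and optional evaluation report) to JSON
#'
#' Serializes the fitted constants, recovered dimensional rate
#' constants, steady states (hidden ones flagged `estimated`), the full
#' chi-square trace, convergence diagnostics, and the effective
#' configuration. Numbers are written at full double precision
#' (~15 significant digits) and round-trip through [read_results()].
#'
#' @param fit a `pendisc_fit`.
#' @param path output JSON path.
#' @param report optional `pendisc_loo` or other list-like report.
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path, report = NULL) {
  stopifnot(inherits(fit, "pendisc_fit"))
  est <- names(fit$X_star) %in% names(fit$X_star_estimated)
  doc <- list(
    free_A = as.list(fit$free_A),
    full_A = as.list(fit$full_A),
    alpha = as.list(fit$alpha),
    beta = as.list(fit$beta),
    X_star = lapply(seq_along(fit$X_star), function(i)
      list(pool = names(fit$X_star)[i], value = fit$X_star[[i]],
           estimated = est[i])),
    hidden = as.list(fit$hidden),
    hidden_x0 = as.list(fit$hidden_x0),
    orders = list(g = fit$model$g, h = fit$model$h),
    chi2 = fit$chi2,
    chi2_trace = fit$chi2_trace,
    iterations = fit$iterations,
    converged = fit$converged,
    criterion = fit$criterion,
    mse = fit$mse,
    constraints = list(
      free = fit$cs$free,
      relations = lapply(fit$cs$relations, function(r)
        paste(paste(r$lhs, collapse = " + "), "=",
              paste(r$rhs, collapse = " + ")))),
    config = unclass(fit$config),
    package_version = as.character(utils::packageVersion("pendisc")))
  if (!is.null(report)) doc$report <- unclass(report)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_results
#' @return `read_results`: the parsed list.
#' @export
read_results <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
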