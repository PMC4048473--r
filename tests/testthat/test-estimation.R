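fx <- branched_reference()
Xs <- steady_state(fx$model)
ts11 <- generate_timeseries(fx, n_points = 11)

test_that("chi-square matches a loop-based recomputation and its edge cases", {
  skel <- build_ssystem(fx$network, "given", g = fx$model$g, h = fx$model$h)
  cs <- derive_constraints(fx$network, Xs)
  dts <- to_dimensionless(ts11, Xs)

  # perfect parameters on noise-free data
  true_free <- c(fx$A_true[["X1"]], fx$A_true[["X4"]])
  expect_lt(chi_square(true_free, dts, skel, cs), 1e-10)

  # random feasible parameters: exact agreement with the brute-force loop
  set.seed(3)
  for (k in 1:3) {
    th <- c(runif(1, 10, 25), runif(1, 4, 12))
    val <- chi_square(th, dts, skel, cs)
    A <- expand_rate_constants(setNames(th, cs$free), cs)
    mod <- pendisc:::dimensionless_model(fx$network, A, skel$g, skel$h, Xs)
    pred <- simulate_model(mod, dts$values[1, ], dts$times,
                           rtol = 1e-8, atol = 1e-10)
    oracle <- brute_chi2(dts$values, pred$values, dts$sigma,
                         colnames(dts$values))
    expect_equal(val, oracle, tolerance = 1e-10)
  }

  # single-point residual d with sigma 1 gives d^2
  one <- timeseries(times = c(0, 1),
                    values = matrix(c(1, 1, 1, 1, 1.3, 1, 1, 1), 2, 4,
                                    byrow = TRUE,
                                    dimnames = list(NULL, colnames(dts$values))),
                    dimensionless = TRUE)
  # model held at steady state (all-ones trajectory): residual only row 2
  v <- chi_square(true_free, one, skel, cs)
  sim <- simulate_model(pendisc:::dimensionless_model(
    fx$network, fx$A_true, skel$g, skel$h, Xs), rep(1, 4), c(0, 1))
  expect_equal(v, sum((one$values[2, ] - sim$values[2, ])^2), tolerance = 1e-12)

  # infeasible expansion returns the +Inf sentinel
  expect_identical(chi_square(c(1, 100), dts, skel, cs), Inf)
})

test_that("Richardson gradient is high-order accurate and falls back one-sided", {
  expect_equal(num_gradient(function(x) x[1]^2, 3), 6, tolerance = 1e-10)
  expect_equal(num_gradient(function(x) exp(x[1]), 0), 1, tolerance = 1e-10)
  g <- num_gradient(function(x) sin(x[1]) * exp(x[2]), c(0.7, -0.3))
  expect_equal(g, c(cos(0.7) * exp(-0.3), sin(0.7) * exp(-0.3)),
               tolerance = 1e-9)
  # function undefined on one side: fallback flagged
  f <- function(x) if (x[1] < 1) NaN else sqrt(x[1] - 1)
  gr <- num_gradient(f, 1 + 1e-7)
  expect_identical(attr(gr, "one_sided"), 1L)
})

test_that("chi-square gradient agrees with an independent high-order stencil", {
  skel <- build_ssystem(fx$network, "given", g = fx$model$g, h = fx$model$h)
  cs <- derive_constraints(fx$network, Xs)
  dts <- to_dimensionless(ts11, Xs)
  f <- function(th) chi_square(th, dts, skel, cs,
                               ode_rtol = 1e-10, ode_atol = 1e-12)
  th0 <- c(14, 8)
  g_pkg <- num_gradient(f, th0)
  # independent oracle: 5-point fourth-order central stencil
  oracle <- vapply(1:2, function(i) {
    h <- 1e-3 * th0[i]
    ev <- function(d) { t2 <- th0; t2[i] <- t2[i] + d; f(t2) }
    (-ev(2 * h) + 8 * ev(h) - 8 * ev(-h) + ev(-2 * h)) / (12 * h)
  }, numeric(1))
  expect_equal(g_pkg, oracle, tolerance = 1e-6 * max(abs(oracle)),
               ignore_attr = TRUE)
})

test_that("LM with true orders recovers the free constants to high precision", {
  fit <- lm_fit(ts11, fx$network, g = fx$model$g, h = fx$model$h, X_star = Xs)
  expect_true(fit$converged)
  expect_identical(fit$criterion, "relative_and_absolute")
  expect_equal(fit$free_A[["X1"]], fx$A_true[["X1"]],
               tolerance = 5e-7)
  expect_equal(fit$free_A[["X4"]], fx$A_true[["X4"]],
               tolerance = 5e-7)
  # chi-square trace never increases over accepted steps
  expect_true(all(diff(fit$chi2_trace) <= 0))
  # expanded vector satisfies the constraints to machine precision
  expect_lt(constraint_residual(fit$cs, fit$full_A), 1e-12)
  # recovered dimensional constants
  expect_equal(unname(fit$alpha), c(12, 8, 3, 2), tolerance = 1e-5)
  expect_equal(unname(fit$beta), c(10, 3, 5, 6), tolerance = 1e-5)
})

test_that("LM agrees with an independent Levenberg-Marquardt implementation", {
  skel <- build_ssystem(fx$network, "given", g = fx$model$g, h = fx$model$h)
  cs <- derive_constraints(fx$network, Xs)
  dts <- to_dimensionless(ts11, Xs)
  obj <- pendisc:::make_objective(fx$network, skel$g, skel$h, cs, dts)
  safe <- function(th) tryCatch(obj$residuals(th),
                                pendisc_infeasible = function(e)
                                  rep(1e6, 44))
  ref <- minpack.lm::nls.lm(par = c(5, 5), fn = safe)
  fit <- lm_fit(ts11, fx$network, g = fx$model$g, h = fx$model$h, X_star = Xs)
  expect_equal(unname(fit$free_A), ref$par, tolerance = 1e-6)
})

test_that("noise-free parameter recovery on random branched trees", {
  for (seed in c(11, 23)) {
    rfx <- random_tree_fixture(5, seed, n_branch = 1)
    rts <- generate_timeseries(rfx, n_points = 11, t_end = 5)
    fit <- lm_fit(rts, rfx$network, g = rfx$model$g, h = rfx$model$h,
                  X_star = rfx$X_star)
    expect_true(fit$converged)
    expect_equal(unname(fit$full_A), unname(rfx$A_true), tolerance = 1e-6)
  }
})

test_that("fixed half-order fit tracks the data satisfactorily", {
  fit <- lm_fit(ts11, fx$network, order_policy = "fixed_half", X_star = Xs)
  expect_true(fit$converged)
  expect_lt(fit$mse, 2e-2)
  expect_true(all(diff(fit$chi2_trace) <= 0))
})

test_that("hidden-pool fit reduces to lm_fit when nothing is hidden", {
  f1 <- lm_fit(ts11, fx$network, g = fx$model$g, h = fx$model$h, X_star = Xs)
  f2 <- fit_with_hidden_pools(ts11, fx$network, g = fx$model$g, h = fx$model$h,
                              X_star = Xs)
  expect_equal(f1$free_A, f2$free_A, tolerance = 1e-12)
  expect_length(f2$hidden, 0L)
})

test_that("hidden-pool fit recovers the hidden steady state with true orders", {
  ts_h <- generate_timeseries(fx, n_points = 11, hidden = "X2")
  expect_false(ts_h$measured[["X2"]])
  Xs_h <- Xs; Xs_h["X2"] <- NA
  fit <- fit_with_hidden_pools(ts_h, fx$network, g = fx$model$g, h = fx$model$h,
                               X_star = Xs_h,
                               hidden_x0 = c(X2 = 2.7 / 2.00607))
  expect_true(fit$converged)
  expect_equal(fit$X_star_estimated[["X2"]], Xs[["X2"]], tolerance = 1e-4)
  expect_equal(unname(fit$full_A), unname(fx$A_true), tolerance = 1e-4)
  # residuals were restricted to measured pools: lm_fit refuses this data
  expect_error(lm_fit(ts_h, fx$network, X_star = Xs_h), "unmeasured")
})

test_that("hidden steady-state relation reproduces the worked example", {
  Xs_r <- branched_Xstar_4dp
  Xs_r["X2"] <- NA
  cs <- derive_constraints(fx$network, Xs_r)
  est <- estimate_hidden_steady_state(
    cs, free_A = c(X1 = 39.62943, X4 = 23.82671), A_hidden = c(X2 = 4.38212))
  expect_equal(est[["X2"]], 2.83721, tolerance = 1e-4)
  # exact constants and steady states recover the true value
  cs2 <- derive_constraints(fx$network, {
    x <- Xs; x["X2"] <- NA; x })
  est2 <- estimate_hidden_steady_state(
    cs2, free_A = c(X1 = fx$A_true[["X1"]], X4 = fx$A_true[["X4"]]),
    A_hidden = c(X2 = fx$A_true[["X2"]]))
  expect_equal(est2[["X2"]], 2.00607, tolerance = 1e-5)
  # branch flux deficit (non-positive numerator) is infeasible
  expect_error(estimate_hidden_steady_state(
    cs, free_A = c(X1 = 1, X4 = 2 * 0.3996 / 0.1428), A_hidden = c(X2 = 1)),
    class = "pendisc_infeasible")
})
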