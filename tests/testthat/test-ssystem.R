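fx <- branched_reference()

test_that("branched benchmark steady state matches its reported values", {
  Xs <- steady_state(fx$model)
  expect_equal(round(unname(Xs), 4), unname(branched_Xstar_4dp))
  expect_equal(unname(Xs["X2"]), 2.00607, tolerance = 1e-5 / 2.00607)
})

test_that("non-dimensionalization reproduces the reference A and B = A", {
  Xs <- steady_state(fx$model)
  dm <- nondimensionalize(fx$model, Xs)
  # printed values derive from slightly rounded steady states
  expect_equal(unname(dm$A), unname(branched_A_ref), tolerance = 1e-6)
  # closed forms implied by the rate law at the steady state
  expect_equal(unname(dm$A),
               c(10 * Xs[["X1"]]^-0.5, 3 * Xs[["X2"]]^-0.25,
                 5 * Xs[["X3"]]^-0.5 * Xs[["X4"]]^0.2, 6 * Xs[["X4"]]^-0.2),
               tolerance = 1e-7)
  # dimensionless right-hand side is exactly zero at x = 1
  r <- pendisc:::dimensionless_rhs(dm)(0, rep(1, 4), NULL)[[1]]
  expect_true(max(abs(r)) < 1e-14)
  expect_equal(unname(steady_state(dm)), rep(1, 4))
})

test_that("nondimensionalize flags an X* that is not a steady state", {
  expect_error(nondimensionalize(fx$model, c(1, 1, 1, 1)), "not a steady state")
})

test_that("A_i equals alpha_i when X* is all-ones", {
  ch <- pathway_network(c("X1", "X2"), list(
    flux("EXTERNAL", "X1"), flux("X1", "X2"), flux("X2", "EXTERNAL")))
  mod <- build_ssystem(ch, "uniform", c = 0.5,
                       alpha = c(1, 1), beta = c(1, 1))
  expect_equal(unname(steady_state(mod)), c(1, 1))
  dm <- nondimensionalize(mod)
  expect_equal(dm$A, mod$alpha, ignore_attr = TRUE)
})

test_that("redimensionalize recovers the generating rate constants", {
  dm <- nondimensionalize(fx$model)
  ab <- redimensionalize(dm)
  expect_equal(unname(ab$alpha), c(12, 8, 3, 2), tolerance = 1e-10)
  expect_equal(unname(ab$beta), c(10, 3, 5, 6), tolerance = 1e-10)
  # reported back-transformed values (printed from a finite-precision fit)
  expect_equal(unname(ab$alpha),
               c(11.999994655, 7.99999807, 3.00000095, 1.99999892),
               tolerance = 1e-5)
  expect_equal(unname(ab$beta),
               c(9.99999555, 2.99999928, 5.00000158, 5.99999676),
               tolerance = 1e-5)
})

test_that("nondimensionalize / redimensionalize round-trip on random chains", {
  for (seed in 1:5) {
    cf <- random_chain(sample(2:6, 1), seed)
    Xs <- steady_state(cf$model)
    dm <- nondimensionalize(cf$model, Xs)
    # independent re-evaluation of the efflux-side definition
    B_hand <- vapply(seq_len(cf$network$n), function(i)
      cf$model$beta[i] * brute_term(1, Xs, cf$model$h[i, ]) / Xs[i], numeric(1))
    expect_equal(unname(dm$A), unname(B_hand), tolerance = 1e-10)
    ab <- redimensionalize(dm)
    expect_equal(unname(ab$alpha), unname(cf$model$alpha), tolerance = 1e-10)
    expect_equal(unname(ab$beta), unname(cf$model$beta), tolerance = 1e-10)
  }
})

test_that("simulation relaxes to the steady state and matches the brute RHS", {
  Xs <- steady_state(fx$model)
  ts <- simulate_model(fx$model, fx$X0, seq(0, 50, length.out = 11))
  expect_lt(max(abs(ts$values[11, ] - Xs) / Xs), 1e-6)
  # vectorized RHS against a loop-based product oracle at random states
  set.seed(42)
  for (k in 1:5) {
    X <- runif(4, 0.1, 3)
    r1 <- pendisc:::ssystem_rhs(fx$model)(0, X, NULL)[[1]]
    expect_equal(unname(r1), unname(brute_rhs(fx$model, X)), tolerance = 1e-12)
  }
})

test_that("simulation commutes with the dimensionless transform", {
  Xs <- steady_state(fx$model)
  dm <- nondimensionalize(fx$model, Xs)
  times <- seq(0, 5, length.out = 11)
  dim_traj <- simulate_model(fx$model, fx$X0, times)
  dimless_traj <- simulate_model(dm, fx$X0 / Xs, times)
  expect_equal(unname(sweep(dim_traj$values, 2, Xs, "/")),
               unname(dimless_traj$values), tolerance = 1e-7)
  # dimensionless steady start stays constant
  flat <- simulate_model(dm, rep(1, 4), times)
  expect_equal(unname(flat$values), matrix(1, 11, 4), tolerance = 1e-9)
})

test_that("perturbed states return monotonically to the steady state tail", {
  dm <- nondimensionalize(fx$model)
  for (p in c("X1", "X3")) {
    x0 <- setNames(rep(1, 4), fx$network$pools$name)
    x0[p] <- 2
    ts <- simulate_model(dm, x0, seq(0, 50, length.out = 101))
    dev <- apply(abs(ts$values - 1), 1, max)
    expect_lt(dev[101], 1e-6)
    tail_dev <- dev[81:101]
    expect_true(all(diff(tail_dev) <= 1e-9))
  }
})

test_that("stiffness ratio matches analytic and brute-force Jacobians", {
  # linear field with eigenvalues -1 and -100
  lin <- function(x) c(-1 * x[1], -100 * x[2])
  expect_equal(stiffness_ratio(lin, c(0, 0))$ratio, 100, tolerance = 1e-8)
  # branched model at steady state vs central-difference Jacobian oracle
  Xs <- steady_state(fx$model)
  sr <- stiffness_ratio(fx$model, Xs)
  f <- function(X) brute_rhs(fx$model, X)
  Jb <- matrix(0, 4, 4)
  hstep <- 1e-6
  for (j in 1:4) {
    Xp <- Xs; Xm <- Xs
    Xp[j] <- Xp[j] + hstep; Xm[j] <- Xm[j] - hstep
    Jb[, j] <- (f(Xp) - f(Xm)) / (2 * hstep)
  }
  ev <- abs(Re(eigen(Jb, only.values = TRUE)$values))
  expect_equal(sr$ratio, max(ev) / min(ev), tolerance = 1e-6)
  expect_warning(stiffness_ratio(fx$model, Xs * 2), "not close to an equilibrium")
})
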