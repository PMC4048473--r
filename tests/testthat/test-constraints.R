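test_that("linear chains reduce to a single free constant", {
  for (n in c(2, 4, 7)) {
    cf <- random_chain(n, seed = n)
    Xs <- steady_state(cf$model)
    cs <- derive_constraints(cf$network, Xs)
    expect_identical(cs$free, "X1")
    expect_identical(count_free_parameters(cf$network), 1L)
    A1 <- cf$A_true[["X1"]]
    A <- expand_rate_constants(c(X1 = A1), cs)
    # chain expansion: A_{i+1} = (X1*/X_{i+1}*) A1, and X1* A1 = Xi* Ai
    expect_equal(unname(A), unname(Xs[["X1"]] / Xs * A1), tolerance = 1e-12)
    expect_equal(unname(A), unname(cf$A_true), tolerance = 1e-8)
    expect_lt(constraint_residual(cs, A), 1e-12)
  }
})

test_that("the branched benchmark frees {A1, A4} and expands by flux balance", {
  fx <- branched_reference()
  Xs <- steady_state(fx$model)
  cs <- derive_constraints(fx$network, Xs)
  expect_identical(cs$free, c("X1", "X4"))
  A <- expand_rate_constants(c(X1 = fx$A_true[["X1"]], X4 = fx$A_true[["X4"]]), cs)
  # A2 = (A1 X1* - A4 X4*)/X2*, A3 = (A1 X1* - A4 X4*)/X3*
  comp <- fx$A_true[["X1"]] * Xs[["X1"]] - fx$A_true[["X4"]] * Xs[["X4"]]
  expect_equal(A[["X2"]], comp / Xs[["X2"]], tolerance = 1e-12)
  expect_equal(A[["X3"]], comp / Xs[["X3"]], tolerance = 1e-12)
  expect_equal(unname(A), unname(fx$A_true), tolerance = 1e-10)

  # printed worked example with rounded steady states
  cs_r <- derive_constraints(fx$network, branched_Xstar_4dp)
  A_r <- expand_rate_constants(c(X1 = 39.62943, X4 = 23.82671), cs_r)
  expect_equal(A_r[["X3"]], 5.57941, tolerance = 1e-4)
  A_ref <- expand_rate_constants(c(X1 = 15.82007531, X4 = 8.85591652), cs_r)
  expect_equal(A_ref[["X2"]], 2.52077734, tolerance = 2e-4)
  expect_equal(A_ref[["X3"]], 2.26931039, tolerance = 2e-4)
})

test_that("infeasible branch subtraction raises a rejection signal", {
  fx <- branched_reference()
  cs <- derive_constraints(fx$network, steady_state(fx$model))
  # A4 X4* >= A1 X1* forces a non-positive derived constant
  expect_error(expand_rate_constants(c(X1 = 1, X4 = 100), cs),
               class = "pendisc_infeasible")
  expect_error(expand_rate_constants(c(X1 = -1, X4 = 1), cs),
               class = "pendisc_infeasible")
})

test_that("confluent structures satisfy the summed flux balance", {
  # X1 and X2 (separate external sources) flow into X3
  net <- pathway_network(c("X1", "X2", "X3"), list(
    flux("EXTERNAL", "X1"), flux("EXTERNAL", "X2"),
    flux("X1", "X3"), flux("X2", "X3"), flux("X3", "EXTERNAL")))
  Xs <- c(X1 = 0.7, X2 = 1.9, X3 = 1.1)
  cs <- derive_constraints(net, Xs)
  expect_length(cs$free, 2L)
  types <- vapply(cs$relations, `[[`, "", "type")
  expect_true("confluence" %in% types)
  fv <- setNames(c(2.5, 0.8), cs$free)
  A <- expand_rate_constants(fv, cs)
  expect_equal(Xs[["X1"]] * A[["X1"]] + Xs[["X2"]] * A[["X2"]],
               Xs[["X3"]] * A[["X3"]], tolerance = 1e-12)
})

test_that("expansion equals brute-force Gaussian elimination on random trees", {
  for (seed in 1:6) {
    n <- sample(4:8, 1)
    fx <- random_tree_fixture(n, seed, n_branch = sample(1:2, 1))
    Xs <- fx$X_star
    cs <- derive_constraints(fx$network, Xs)
    # free count == rank deficiency of the relation system (brute force)
    R <- cs$R
    expect_identical(length(cs$free), n - qr(R)$rank)
    expect_identical(length(cs$free), count_free_parameters(fx$network))
    # expansion satisfies every relation at random positive free values
    set.seed(seed + 100)
    fv <- setNames(runif(length(cs$free), 0.5, 4), cs$free)
    A <- tryCatch(expand_rate_constants(fv, cs),
                  pendisc_infeasible = function(e) NULL)
    if (!is.null(A)) expect_lt(constraint_residual(cs, A), 1e-12)
    # brute force: solve the full linear system R Y = 0 with Y_free pinned,
    # via base-R qr on the stacked system
    if (!is.null(A)) {
      nm <- fx$network$pools$name
      pin <- matrix(0, length(cs$free), n, dimnames = list(NULL, nm))
      for (i in seq_along(cs$free)) pin[i, cs$free[i]] <- 1
      lhs <- rbind(R, pin)
      rhs <- c(rep(0, nrow(R)), Xs[cs$free] * fv)
      Y <- qr.solve(lhs, rhs)
      expect_equal(unname(A), unname(Y / Xs), tolerance = 1e-10)
    }
    # the true dimensionless constants satisfy the constraints
    expect_lt(constraint_residual(cs, fx$A_true), 1e-10)
  }
})

test_that("aspartate topology reduces seven constants to two", {
  fx <- aspartate_network()
  expect_identical(count_free_parameters(fx$network), 2L)
  expect_identical(parameter_count(7, "dimensionless"), 7)
  cs <- derive_constraints(fx$network, setNames(rep(1, 7), paste0("X", 1:7)))
  # branch constraint at X2 with two downstream fluxes
  br <- Filter(function(r) r$type == "branch", cs$relations)
  expect_length(br, 1L)
  expect_identical(br[[1]]$lhs, "X2")
  expect_setequal(br[[1]]$rhs, c("X3", "X4"))
  # regulation changes orders only, never the constraint count
  expect_identical(count_free_parameters(aspartate_network(regulation = TRUE)$network), 2L)
})

test_that("parameter counts follow the reduction ladder", {
  expect_equal(parameter_count(4, "full_ssystem"), 40)
  expect_equal(parameter_count(4, "fixed_orders"), 8)
  expect_equal(parameter_count(4, "dimensionless"), 4)
  expect_equal(parameter_count(7, "constrained", p = 1), 2)
  expect_equal(parameter_count(9, "constrained", p = 3), 4)
})
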