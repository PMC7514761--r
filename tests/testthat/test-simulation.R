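test_that("gauss_hermite integrates polynomials exactly", {
  rule <- gauss_hermite(8)
  # moments of exp(-x^2): integral of x^k is Gamma((k+1)/2) for even k
  for (k in c(0, 2, 4, 6, 8)) {
    expect_equal(sum(rule$weights * rule$nodes^k), gamma((k + 1) / 2),
                 tolerance = 1e-12)
  }
  for (k in c(1, 3, 5)) {
    expect_equal(sum(rule$weights * rule$nodes^k), 0, tolerance = 1e-12)
  }
  # normal expectations: E[Y^2] under N(m, v)
  expect_equal(auxselect:::gh_expect(function(y) y^2, 1.5, 0.3, rule),
               0.3 + 1.5^2, tolerance = 1e-12)
})

test_that("generate_case reproduces the stated moments", {
  d1 <- generate_case("case1", 1e6, seed = 101L)
  se3 <- function(s) 3 * s / sqrt(1e6)
  expect_lt(abs(mean(d1$z) - 0.6), se3(sqrt(0.24)))
  expect_lt(abs(var(d1$y[d1$z == 1]) - 0.7), 0.01)
  expect_lt(abs(var(d1$y[d1$z == 0]) - 0.7), 0.01)
  expect_lt(abs(mean(d1$y[d1$z == 1]) + 1.2), 0.01)
  # Case 1: E[a(2z - 1)] = 1.8
  expect_lt(abs(mean(d1$a * (2 * d1$z - 1)) - 1.8), 0.01)
  d2 <- generate_case("case2", 1e6, seed = 102L)
  expect_lt(abs(cor(d2$a, d2$y)), se3(1))
  expect_lt(abs(cor(d2$a, d2$z)), se3(1))
})

test_that("paired generation shares the primary stream", {
  dd <- generate_case(n = 300L, seed = 103L, paired = TRUE)
  expect_identical(dd$case1$y, dd$case2$y)
  expect_identical(dd$case1$z, dd$case2$z)
  expect_false(isTRUE(all.equal(dd$case1$a, dd$case2$a)))
})

test_that("true_loss_x matches the closed-form oracle and its symmetries", {
  rule <- gauss_hermite(64)
  th0 <- theta0()
  # quadrature vs the closed-form normal cross-entropy
  expect_equal(true_loss_x(th0, align = FALSE), oracle_loss_x(th0),
               tolerance = 1e-10)
  set.seed(104)
  for (k in 1:10) {
    p <- random_params(aux = FALSE)
    expect_equal(true_loss_x(p, align = FALSE), oracle_loss_x(p),
                 tolerance = 1e-8)
    # quadrature refinement: 64 vs 128 nodes
    expect_equal(true_loss_x(p, nodes = 64L), true_loss_x(p, nodes = 128L),
                 tolerance = 1e-10)
    # alignment symmetry and Gibbs' inequality
    expect_equal(true_loss_x(p), true_loss_x(swap_components(p)),
                 tolerance = 1e-12)
    expect_gte(true_loss_x(p), true_loss_x(th0, align = FALSE) - 1e-10)
    expect_gte(true_loss_y(p), true_loss_y(th0) - 1e-10)
  }
  # refinement for the observed-data loss (the log-mixture integrand is not
  # polynomial, so convergence is slower than for the complete-data loss)
  expect_equal(true_loss_y(th0, nodes = 64L), true_loss_y(th0, nodes = 128L),
               tolerance = 1e-8)
})

test_that("the losses decompose as Lx = Ly + conditional cross-entropy", {
  th0 <- theta0()
  rule <- gauss_hermite(96)
  cond <- function(y) {
    post_true <- posterior_z(th0, y)
    -rowSums(ifelse(post_true == 0, 0, post_true * log(post_true)))
  }
  ce <- 0.6 * auxselect:::gh_expect(cond, -1.2, 0.7, rule) +
        0.4 * auxselect:::gh_expect(cond, 1.2, 0.7, rule)
  expect_equal(true_loss_x(th0, align = FALSE), true_loss_y(th0) + ce,
               tolerance = 1e-8)
  expect_gte(ce, 0)
})

test_that("experiment runners are reproducible and internally consistent", {
  cfg <- experiment_config(n_per_dataset = 100L, n_replicates = 8L,
                           seed = 105L)
  r1 <- run_full_experiment(cfg)
  r2 <- run_full_experiment(cfg)
  expect_identical(r1, r2)
  expect_identical(run_bias_experiment(cfg), r1$bias)
  sel <- run_selection_experiment(cfg)
  expect_identical(sel$selection, r1$selection)
  expect_identical(sel$risk, r1$risk)
  # the y-only estimator's risk row is shared between the cases
  expect_equal(r1$risk$risk_y[r1$risk$case == "case1"],
               r1$risk$risk_y[r1$risk$case == "case2"])
  expect_equal(r1$selection$n_select_b + r1$selection$n_select_y, rep(8, 2))
  m <- r1$raw[["100"]]
  # the selected estimator's loss is the selected branch, replicate-wise
  expect_equal(m[, "ex_best1"],
               ifelse(m[, "sel1"] == 1, m[, "ex_b1"], m[, "ex_y"]))
})

test_that("the experiment config validates its inputs", {
  expect_error(experiment_config(n_replicates = 10), "seed")
  expect_error(experiment_config(n_per_dataset = 5L, seed = 1), "n_per_dataset")
})
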