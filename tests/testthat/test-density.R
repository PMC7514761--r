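test_that("logdensity_joint matches the two-term bivariate oracle", {
  b0 <- beta0()
  for (pt in list(c(-1.2, 1.8), c(0, 0), c(2.5, -1))) {
    expect_equal(logdensity_joint(b0, pt[1], pt[2]),
                 log(oracle_joint_density(b0, pt[1], pt[2])),
                 tolerance = 1e-12)
  }
  # mixture collapses to one bivariate normal when the components coincide
  p <- gmm_params(0.5, 0.3, 0.3, 1.1, -0.2, -0.2, 0.8, 0.25)
  S <- matrix(c(1.1, 0.25, 0.25, 0.8), 2, 2)
  expect_equal(logdensity_joint(p, 0.7, -0.4),
               log(oracle_dbnorm(c(0.7, -0.4), c(0.3, -0.2), S)),
               tolerance = 1e-12)
})

test_that("joint density integrates to one and marginalizes to the y-density", {
  b0 <- beta0()
  total <- integrate(function(y) vapply(y, function(yi)
    integrate(function(a) exp(logdensity_joint(b0, rep(yi, length(a)), a)),
              -Inf, Inf, rel.tol = 1e-10)$value, numeric(1)),
    -Inf, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-7)
  for (yi in c(-1.2, 0, 1.7)) {
    marg <- integrate(function(a)
      exp(logdensity_joint(b0, rep(yi, length(a)), a)),
      -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(marg, exp(logdensity_y(b0, yi)), tolerance = 1e-8)
  }
})

test_that("logdensity_y matches the univariate mixture oracle", {
  th <- theta0()
  for (yi in c(-1.2, 0, 3)) {
    expect_equal(logdensity_y(th, yi), log(oracle_y_density(th, yi)),
                 tolerance = 1e-12)
  }
  # symmetric two-term mixture at the midpoint: both terms equal
  p <- gmm_params(0.5, -0.9, 0.9, 0.5)
  expect_equal(logdensity_y(p, 0),
               log(oracle_y_density(p, 0)), tolerance = 1e-14)
  expect_equal(exp(logdensity_y(p, 0)),
               dnorm(0, -0.9, sqrt(0.5)), tolerance = 1e-14)
})

test_that("label-swap invariance holds for observable-data densities", {
  set.seed(31)
  for (k in 1:25) {
    p <- random_params(aux = TRUE)
    ps <- swap_components(p)
    y <- rnorm(5); a <- rnorm(5)
    expect_equal(logdensity_joint(p, y, a), logdensity_joint(ps, y, a),
                 tolerance = 1e-12)
    expect_equal(logdensity_y(p, y), logdensity_y(ps, y), tolerance = 1e-12)
  }
})

test_that("logdensity_x has the stated closed form and sums to the marginal", {
  th <- theta0()
  expect_equal(logdensity_x(th, -1.2, 1),
               log(0.6) + dnorm(-1.2, -1.2, sqrt(0.7), log = TRUE),
               tolerance = 1e-14)
  expect_equal(logdensity_x(th, 0.4, 0),
               log(0.4) + dnorm(0.4, 1.2, sqrt(0.7), log = TRUE),
               tolerance = 1e-14)
  set.seed(32)
  for (k in 1:10) {
    p <- random_params(aux = FALSE)
    y <- rnorm(7)
    tot <- exp(logdensity_x(p, y, rep(1, 7))) + exp(logdensity_x(p, y, rep(0, 7)))
    expect_equal(log(tot), logdensity_y(p, y), tolerance = 1e-10)
  }
  # exchangeable components
  p <- gmm_params(0.5, 0.7, 0.7, 1.3)
  expect_equal(logdensity_x(p, 1.1, 1), logdensity_x(p, 1.1, 0),
               tolerance = 1e-14)
  expect_error(logdensity_x(th, 0, 2), "0 or 1")
})

test_that("posterior_z is a Bayes rule on the two component densities", {
  p <- gmm_params(0.5, -0.8, 0.8, 0.6)
  expect_equal(drop(posterior_z(p, 0)), c(z1 = 0.5, z0 = 0.5),
               tolerance = 1e-14)
  b0 <- beta0()
  S <- matrix(c(0.7, 0, 0, 0.49), 2, 2)
  n1 <- 0.6 * oracle_dbnorm(c(-1.2, 1.8), c(-1.2, 1.8), S)
  n2 <- 0.4 * oracle_dbnorm(c(-1.2, 1.8), c(1.2, -1.8), S)
  expect_equal(unname(posterior_z(b0, -1.2, 1.8)[1, "z1"]), n1 / (n1 + n2),
               tolerance = 1e-12)
  set.seed(33)
  for (k in 1:10) {
    pp <- random_params(aux = TRUE)
    y <- rnorm(6); a <- rnorm(6)
    post <- posterior_z(pp, y, a)
    expect_true(all(post >= 0))
    expect_equal(rowSums(post), rep(1, 6), tolerance = 1e-12)
  }
})

test_that("invalid parameters are rejected", {
  expect_error(gmm_params(1.2, 0, 1, 1), "pi1")
  expect_error(gmm_params(0.5, 0, 1, -1), "positive")
  # |cov| >= sqrt(var product) breaks positive definiteness
  expect_error(gmm_params(0.5, 0, 1, 1, 0, 1, 1, 1.01), "positive definite")
  expect_error(logdensity_joint(theta0(), 0, 0), "no auxiliary")
})
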