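test_that("EM recovers the Case 1 truth at n = 2000", {
  d <- generate_case("case1", 2000L, seed = 7L)
  fit <- fit_gmm(d, use_auxiliary = TRUE, control = fit_control(seed = 8L))
  th <- align_to_truth(fit$params)
  expect_true(fit$converged)
  expect_lt(abs(th$pi1 - 0.6), 0.1)
  expect_lt(abs(th$mu1y - (-1.2)), 0.1)
  expect_lt(abs(th$mu2y - 1.2), 0.1)
  expect_lt(abs(th$sigma_y2 - 0.7), 0.1)
  # nuisance block too (the model is correctly specified in Case 1)
  expect_lt(abs(th$mu1a - 1.8), 0.1)
  expect_lt(abs(th$sigma_a2 - 0.49), 0.1)
})

test_that("fit invariants: monotone trace, consistent loglik, proper rows", {
  set.seed(41)
  for (k in 1:5) {
    d <- generate_case(sample(c("case1", "case2"), 1), 150L)
    fit <- fit_gmm(d, use_auxiliary = TRUE)
    expect_true(all(diff(fit$trace) >= -1e-9))
    expect_equal(fit$loglik_per_obs,
                 mean(logdensity_joint(fit$params, d$y, d$a)),
                 tolerance = 1e-8)
    expect_equal(rowSums(fit$responsibilities), rep(1, d$n),
                 tolerance = 1e-10)
    fy <- fit_gmm(d, use_auxiliary = FALSE)
    expect_true(all(diff(fy$trace) >= -1e-9))
    expect_equal(fy$loglik_per_obs, mean(logdensity_y(fy$params, d$y)),
                 tolerance = 1e-8)
    expect_false(has_aux(fy$params))
    # responsibilities at convergence agree with the posterior operation
    expect_equal(fit$responsibilities, posterior_z(fit$params, d$y, d$a))
  }
})

test_that("separated clusters are recovered essentially exactly", {
  set.seed(42)
  n <- 200L
  z <- rbinom(n, 1, 0.5)
  y <- rnorm(n, ifelse(z == 1, 0, 20), 1)  # 20 sigma apart
  d <- aux_dataset(y)
  fit <- fit_gmm(d, use_auxiliary = FALSE, control = fit_control(seed = 43L))
  th <- if (fit$params$mu1y < fit$params$mu2y) fit$params else
    swap_components(fit$params)
  expect_lt(abs(th$mu1y - mean(y[z == 1])), 1e-3)
  expect_lt(abs(th$mu2y - mean(y[z == 0])), 1e-3)
  post <- posterior_z(th, y)[, 1L]
  expect_true(all(abs(post - z) < 1e-6))
})

test_that("degenerate and undersized inputs raise errors", {
  # two exact point masses: pooled variance collapses to the floor
  d <- aux_dataset(rep(c(0, 2), each = 10))
  expect_error(fit_gmm(d, use_auxiliary = FALSE), "degenerate")
  expect_error(fit_gmm(aux_dataset(1:3), use_auxiliary = FALSE), "at least 5")
  expect_error(fit_gmm(aux_dataset(rnorm(10)), use_auxiliary = TRUE),
               "no auxiliary")
})

test_that("fit_complete matches hand-computed and optimizer oracles", {
  d <- aux_dataset(y = c(-1, 1, -1, 1), z = c(1, 1, 0, 0))
  fit <- fit_complete(d)
  expect_equal(fit$params$pi1, 0.5)
  expect_equal(fit$params$mu1y, 0)
  expect_equal(fit$params$mu2y, 0)
  expect_equal(fit$params$sigma_y2, 1)

  # exact-fit toy collapses to zero variance -> degenerate
  expect_error(fit_complete(aux_dataset(c(0, 0, 2, 2), z = c(1, 1, 0, 0))),
               "degenerate")
  expect_error(fit_complete(aux_dataset(rnorm(4), z = rep(1, 4))), "empty")

  # brute-force maximization of the complete-data log-likelihood
  set.seed(44)
  z <- rbinom(20, 1, 0.6)
  y <- rnorm(20, ifelse(z == 1, -1, 1), 0.8)
  d <- aux_dataset(y, z = z)
  fit <- fit_complete(d)
  obj <- function(par) {
    p <- gmm_params(plogis(par[1]), par[2], par[3], exp(par[4]))
    -sum(logdensity_x(p, y, z))
  }
  opt <- optim(c(0, -1, 1, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(qlogis(fit$params$pi1), opt$par[1], tolerance = 1e-4)
  expect_equal(fit$params$mu1y, opt$par[2], tolerance = 1e-5)
  expect_equal(fit$params$mu2y, opt$par[3], tolerance = 1e-5)
  expect_equal(log(fit$params$sigma_y2), opt$par[4], tolerance = 1e-4)
  expect_lte(-opt$value, sum(logdensity_x(fit$params, y, z)) + 1e-6)
})
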