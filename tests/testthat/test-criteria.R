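test_that("scalar-matrix oracles fix the criterion arithmetic", {
  # 1x1 'matrices': Ib = 2, Jb = 2, Kby = 1, Ix - Iy = 0.5, n = 10, elly = -1
  m <- as_info_matrices(I_b = 2, J_b = 2, I_x = 1.5, I_y = 1, K_by = 1,
                        n = 10)
  r <- criterion_from_matrices("RISKHAT_xb", elly = -1, m)
  # 20 + 2*(1/2)*1 + 0.5*(1/2)*2*(1/2) = 21.25 by hand
  expect_equal(r$value, 21.25, tolerance = 1e-12)
  expect_equal(r$goodness_term, 20)
  expect_equal(r$value, r$goodness_term + sum(unlist(r$penalty_terms)),
               tolerance = 1e-12)

  a_yb <- criterion_from_matrices("AIC_yb", elly = -1, m)
  expect_equal(a_yb$value, 20 + 2 * 0.5, tolerance = 1e-12)
  a_xb <- criterion_from_matrices("AIC_xb", elly = -1, m)
  expect_equal(a_xb$value, 20 + 1.5 / 2 + 0.5, tolerance = 1e-12)
  # the latent surcharge identity in scalars
  expect_equal(a_xb$value - a_yb$value, 0.5 / 2, tolerance = 1e-12)
})

test_that("AIC_yy has penalty 2d and an independently recomputed goodness", {
  sh <- shared_case1_mid()
  cr <- ic_aic_yy(sh$fit_y, sh$base)
  expect_equal(cr$penalty_terms[["2d"]], 8)
  oracle_good <- -2 * sum(log(oracle_y_density(sh$fit_y$params, sh$base$y)))
  expect_equal(cr$goodness_term, oracle_good, tolerance = 1e-8)
  expect_equal(cr$value, oracle_good + 8, tolerance = 1e-8)
})

test_that("the reduction lattice holds numerically", {
  sh <- shared_case1_mid()
  tol <- 1e-8
  # X = B = Y: the robust criterion collapses to TIC
  tic <- ic_tic(sh$fit_y, sh$mats_y, sh$base)
  mats_y_nolat <- info_matrices(sh$fit_y, sh$base, latent = FALSE)
  red <- criterion_from_matrices("RISKHAT_xb", elly_of_fit(sh$fit_y, sh$base),
                                 mats_y_nolat)
  expect_equal(red$value, tic$value, tolerance = tol)

  # X = Y: AIC_xb collapses to AIC_yb
  mats_b_nolat <- info_matrices(sh$fit_b, sh$data, latent = FALSE)
  xb_red <- criterion_from_matrices("AIC_xb", elly_of_fit(sh$fit_b, sh$data),
                                    mats_b_nolat)
  yb <- ic_aic_yb(sh$fit_b, sh$mats_b, sh$data)
  expect_equal(xb_red$value, yb$value, tolerance = tol)

  # B = Y: AIC_yb collapses to AIC_yy
  yb_red <- criterion_from_matrices("AIC_yb", elly_of_fit(sh$fit_y, sh$base),
                                    sh$mats_y)
  expect_equal(yb_red$value, ic_aic_yy(sh$fit_y, sh$base)$value,
               tolerance = tol)

  # X = Y on the no-auxiliary side: AIC_xy collapses to AIC_yy
  xy_red <- criterion_from_matrices("AIC_xy", elly_of_fit(sh$fit_y, sh$base),
                                    mats_y_nolat)
  expect_equal(xy_red$value, ic_aic_yy(sh$fit_y, sh$base)$value,
               tolerance = tol)
})

test_that("AIC_xb - AIC_yb equals the latent-penalty trace", {
  sh <- shared_case1_mid()
  xb <- ic_aic_xb(sh$fit_b, sh$mats_b, sh$data)
  yb <- ic_aic_yb(sh$fit_b, sh$mats_b, sh$data)
  t_zy <- sum(diag(solve(sh$mats_b$I_b, sh$mats_b$I_zy)))
  expect_equal(xb$value - yb$value, t_zy, tolerance = 1e-8)
  expect_gt(t_zy, -1e-8)
})

test_that("robust and simplified criteria agree under correct specification", {
  sh <- shared_case1_big()
  r <- ic_risk_xb(sh$fit_b, sh$mats_b, sh$data)
  a <- ic_aic_xb(sh$fit_b, sh$mats_b, sh$data)
  pen <- sum(unlist(a$penalty_terms))
  expect_lt(abs(r$value - a$value), 0.15 * pen)
  # TIC penalty approaches 2d for the correctly specified y-model
  tic <- ic_tic(sh$fit_y, sh$mats_y, aux_dataset(sh$data$y))
  expect_equal(tic$penalty_terms[[1]], 8, tolerance = 0.8)
})

test_that("derivative engine choice does not move AIC_xy materially", {
  d <- generate_case("case1", 100L, seed = 71L)
  base <- aux_dataset(d$y)
  fit <- fit_gmm(base, use_auxiliary = FALSE, control = fit_control(seed = 72L))
  mats_fast <- info_matrices(fit, base)
  sc_num <- grad_loglik("y", fit$params, base$y, method = "numeric")
  mats_num <- as_info_matrices(I_b = mats_fast$I_b,
                               J_b = crossprod(sc_num) / base$n,
                               I_x = mats_fast$I_x, I_y = mats_fast$I_y,
                               K_by = crossprod(sc_num, sc_num) / base$n,
                               n = base$n)
  v1 <- criterion_from_matrices("AIC_xy", elly_of_fit(fit, base), mats_fast)
  v2 <- criterion_from_matrices("AIC_xy", elly_of_fit(fit, base), mats_num)
  expect_equal(v1$value, v2$value, tolerance = 1e-4)
})

test_that("select_auxiliary keeps a useful variable, drops pure noise", {
  d <- generate_case("case1", 500L, seed = 73L)
  df <- as.data.frame(d)
  set.seed(74)
  df$noise <- rnorm(500)
  df$flat <- rep(1, 500)  # constant: EM must fail, candidate excluded
  expect_warning(
    res <- select_auxiliary(df, primary = "y",
                            candidates = c("a", "noise", "flat"),
                            target = "x", seed = 75),
    "excluded")
  expect_equal(res$best_label, "a")
  expect_true(res$candidates$failed[res$candidates$label == "flat"])
  expect_equal(sum(res$candidates$failed), 1L)
  # the y-target comparison applies its rule consistently (whether the
  # auxiliary helps in predicting Y only is a much closer call than for X)
  res_y <- select_auxiliary(df, primary = "y", candidates = "a",
                            target = "y", seed = 76)
  vals <- res_y$candidates
  expected_best <- if (vals$value[vals$label == "a"] <
                         vals$value[vals$label == "<none>"]) "a" else "<none>"
  expect_equal(res_y$best_label, expected_best)
  expect_setequal(vals$criterion, c("AIC_yy", "AIC_yb"))
})

test_that("pure-noise auxiliaries are rejected in most replicates", {
  set.seed(77)
  rejected <- 0L
  for (k in 1:8) {
    d <- generate_case("case2", 500L)
    res <- select_auxiliary(as.data.frame(d), primary = "y",
                            candidates = "a", target = "x")
    if (res$best_label == "<none>") rejected <- rejected + 1L
  }
  expect_gte(rejected, 6L)
})
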