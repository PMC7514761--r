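#' Generate a dataset from the simulation truth
#'
#' Draws \eqn{Z \sim Bernoulli(0.6)}, \eqn{Y | Z \sim N(\mp 1.2, 0.7)} and the
#' auxiliary variable per case (see \code{\link{true_model}}).  In paired
#' mode both auxiliary columns are produced from one \eqn{(y, z)} stream, so
#' the two cases share identical primary data — the design used to make the
#' case-wise risk rows directly comparable.  The draw order is fixed
#' (z, y, a1, then the Case 2 mixture labels and a2), so paired and
#' single-case streams are reproducible from the seed.
#'
#' @param case_id \code{"case1"} or \code{"case2"} (ignored when
#'   \code{paired}).
#' @param n Sample size.
#' @param seed Optional integer seed; \code{NULL} uses the current stream.
#' @param paired Return both auxiliary columns.
#' @return An \code{"aux_dataset"} with \code{y}, \code{a}, \code{z}; in
#'   paired mode a list with elements \code{case1} and \code{case2} (sharing
#'   \code{y} and \code{z}).
#' @export
generate_case <- function(case_id = c("case1", "case2"), n, seed = NULL,
                          paired = FALSE) {
  case_id <- match.arg(case_id)
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tm <- true_model()
  z <- stats::rbinom(n, 1L, tm$pi1)
  y <- stats::rnorm(n, mean = ifelse(z == 1, tm$mu_y[1L], tm$mu_y[2L]),
                    sd = sqrt(tm$var_y))
  draw_a <- function(lab) {
    stats::rnorm(n, mean = ifelse(lab == 1, tm$mu_a[1L], tm$mu_a[2L]),
                 sd = sqrt(tm$var_a))
  }
  if (paired) {
    a1 <- draw_a(z)
    w <- stats::rbinom(n, 1L, tm$pi1)  # independent labels for Case 2
    a2 <- draw_a(w)
    return(list(case1 = aux_dataset(y, a1, z),
                case2 = aux_dataset(y, a2, z)))
  }
  a <- if (case_id == "case1") draw_a(z) else draw_a(stats::rbinom(n, 1L, tm$pi1))
  aux_dataset(y, a, z)
}

#' Configuration of a simulation experiment
#'
#' @param n_per_dataset Integer vector of sample sizes.
#' @param n_replicates Number of replicate datasets per sample size.
#' @param seed Master integer seed (mandatory); one independent substream is
#'   derived per replicate so serial and chunked runs agree.
#' @param cases Which cases to run.
#' @param quadrature_nodes Gauss-Hermite nodes per component for the loss
#'   integrals.
#' @param control A \code{\link{fit_control}} for every EM fit.
#' @return A list of class \code{"experiment_config"}.
#' @export
experiment_config <- function(n_per_dataset = c(100L, 500L),
                              n_replicates = 2000L, seed,
                              cases = c("case1", "case2"),
                              quadrature_nodes = 64L,
                              control = fit_control()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_replicates >= 1L, all(n_per_dataset >= 10L))
  structure(list(n_per_dataset = as.integer(n_per_dataset),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), cases = cases,
                 quadrature_nodes = as.integer(quadrature_nodes),
                 control = control),
            class = "experiment_config")
}

## independent per-replicate substream seeds from the master seed
replicate_seeds <- function(seed, t) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, t)
}

## One replicate of the full paired experiment at sample size n: generates
## paired data, fits the y-only and both joint models, and returns the
## criterion differences, selections, and aligned excess losses.
replicate_stats <- function(n, rep_seed, control, rule, lx0) {
  set.seed(rep_seed)
  dd <- generate_case(n = n, seed = NULL, paired = TRUE)
  d1 <- dd$case1; d2 <- dd$case2
  base <- aux_dataset(d1$y)

  fit_y <- fit_gmm(base, use_auxiliary = FALSE, control = control)
  mats_y <- info_matrices(fit_y, base)
  aic_xy <- criterion_from_matrices("AIC_xy", elly_of(fit_y, base), mats_y)

  one_case <- function(d) {
    fit_b <- fit_gmm(d, use_auxiliary = TRUE, control = control)
    mats_b <- info_matrices(fit_b, d)
    aic_xb <- criterion_from_matrices("AIC_xb", elly_of(fit_b, d), mats_b)
    list(d_aic = aic_xb$value - aic_xy$value,
         ex_b = 2 * n * (true_loss_x(fit_b$params, rule = rule) - lx0))
  }
  c1 <- one_case(d1)
  c2 <- one_case(d2)
  ex_y <- 2 * n * (true_loss_x(fit_y$params, rule = rule) - lx0)
  c(d_aic1 = c1$d_aic, d_aic2 = c2$d_aic,
    sel1 = as.numeric(c1$d_aic < 0), sel2 = as.numeric(c2$d_aic < 0),
    ex_b1 = c1$ex_b, ex_b2 = c2$ex_b, ex_y = ex_y,
    ex_best1 = if (c1$d_aic < 0) c1$ex_b else ex_y,
    ex_best2 = if (c2$d_aic < 0) c2$ex_b else ex_y)
}

## run all replicates at one n; returns a T x 9 matrix
run_replicates <- function(n, config) {
  rule <- gauss_hermite(config$quadrature_nodes)
  lx0 <- true_loss_x(true_model()$theta0, rule = rule, align = FALSE)
  seeds <- replicate_seeds(config$seed + n, config$n_replicates)
  out <- matrix(NA_real_, config$n_replicates, 9L)
  for (t in seq_len(config$n_replicates))
    out[t, ] <- replicate_stats(n, seeds[t], config$control, rule, lx0)
  colnames(out) <- c("d_aic1", "d_aic2", "sel1", "sel2",
                     "ex_b1", "ex_b2", "ex_y", "ex_best1", "ex_best2")
  out
}

mc_se <- function(x) stats::sd(x) / sqrt(length(x))

#' Unbiasedness experiment: criterion difference vs. true risk difference
#'
#' For each sample size, simulates Case 1 replicates, fits the joint and
#' y-only models, and compares the simulation average of
#' \eqn{AIC_{x;b} - AIC_{x;y}} with the Monte-Carlo estimate of
#' \eqn{2n\{R_x(\hat\theta_b) - R_x(\hat\theta_y)\}} (losses by quadrature
#' with label alignment).  Under correct specification the two columns agree
#' asymptotically — the unbiasedness property of the criterion.
#'
#' @param config An \code{\link{experiment_config}}.
#' @return A data frame with one row per sample size: means and Monte-Carlo
#'   standard errors of the criterion difference and the scaled risk
#'   difference.
#' @export
run_bias_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- lapply(config$n_per_dataset, function(n)
    summarize_bias(run_replicates(n, config), n, config$n_replicates))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-pass run of the full paired experiment
#'
#' Computes the bias table of \code{\link{run_bias_experiment}} and the
#' selection/risk tables of \code{\link{run_selection_experiment}} from one
#' shared replicate stream (each replicate is generated, fitted, and scored
#' once).  This is the entry point used by the acceptance report, where all
#' summaries refer to the same Monte-Carlo sample.
#'
#' @param config An \code{\link{experiment_config}}.
#' @return A list with \code{bias}, \code{selection}, \code{risk} data frames
#'   and the per-replicate matrices in \code{raw} (one per sample size).
#' @export
run_full_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  raw <- lapply(config$n_per_dataset, run_replicates, config = config)
  names(raw) <- as.character(config$n_per_dataset)
  bias <- do.call(rbind, Map(summarize_bias, raw, config$n_per_dataset,
                             MoreArgs = list(T_ = config$n_replicates)))
  sel <- do.call(rbind, Map(summarize_selection, raw, config$n_per_dataset,
                            MoreArgs = list(T_ = config$n_replicates,
                                            cases = config$cases)))
  risk <- do.call(rbind, Map(summarize_risk, raw, config$n_per_dataset,
                             MoreArgs = list(T_ = config$n_replicates,
                                             cases = config$cases)))
  rownames(bias) <- rownames(sel) <- rownames(risk) <- NULL
  list(bias = bias, selection = sel, risk = risk, raw = raw)
}

summarize_bias <- function(m, n, T_) {
  d_risk <- m[, "ex_b1"] - m[, "ex_y"]
  data.frame(n = n,
             mean_aic_diff = mean(m[, "d_aic1"]),
             se_aic_diff = mc_se(m[, "d_aic1"]),
             mean_risk_diff = mean(d_risk),
             se_risk_diff = mc_se(d_risk),
             T = T_)
}

summarize_selection <- function(m, n, T_, cases) {
  do.call(rbind, lapply(cases, function(case) {
    i <- if (case == "case1") 1L else 2L
    sel <- m[, paste0("sel", i)]
    data.frame(case = case, n = n, T = T_,
               n_select_b = sum(sel), n_select_y = T_ - sum(sel),
               frac_select_b = mean(sel))
  }))
}

summarize_risk <- function(m, n, T_, cases) {
  do.call(rbind, lapply(cases, function(case) {
    i <- if (case == "case1") 1L else 2L
    ex_b <- m[, paste0("ex_b", i)]
    ex_best <- m[, paste0("ex_best", i)]
    data.frame(case = case, n = n, T = T_,
               risk_b = mean(ex_b), se_b = mc_se(ex_b),
               risk_y = mean(m[, "ex_y"]), se_y = mc_se(m[, "ex_y"]),
               risk_best = mean(ex_best), se_best = mc_se(ex_best))
  }))
}

#' Selection experiment: frequencies and risk of the selected estimator
#'
#' Runs the paired two-case experiment: per replicate the auxiliary variable
#' is selected iff \eqn{AIC_{x;b} < AIC_{x;y}}, and the selected estimator
#' \eqn{\hat\theta_{best}} is scored by its aligned excess complete-data
#' loss.  Reports, per case and sample size, the selection counts and the
#' estimated excess risks \eqn{2n\{R_x(\hat\theta) - L_x(\theta_0)\}} for the
#' joint, y-only, and selected estimators, with Monte-Carlo standard errors.
#' The y-only row is identical across cases by the shared (y, z) stream.
#'
#' @param config An \code{\link{experiment_config}}.
#' @return A list with data frames \code{selection} (counts, scaled to the
#'   replicate number) and \code{risk}.
#' @export
run_selection_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  sel_rows <- list(); risk_rows <- list()
  for (n in config$n_per_dataset) {
    m <- run_replicates(n, config)
    sel_rows[[length(sel_rows) + 1L]] <-
      summarize_selection(m, n, config$n_replicates, config$cases)
    risk_rows[[length(risk_rows) + 1L]] <-
      summarize_risk(m, n, config$n_replicates, config$cases)
  }
  out <- list(selection = do.call(rbind, sel_rows),
              risk = do.call(rbind, risk_rows))
  rownames(out$selection) <- rownames(out$risk) <- NULL
  out
}
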