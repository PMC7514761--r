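## The information-criteria family.  All criteria are reported on the
## 2n-scale: value = -2 n * (average Y-marginal log-likelihood) + penalties,
## so values are directly comparable across criteria and with published
## simulation tables.

tr <- function(M) sum(diag(M))

#' Assemble an information-matrices object from raw matrices
#'
#' Low-level constructor used for hand-built (e.g. scalar) matrix sets in
#' tests and diagnostics; \code{\link{info_matrices}} is the estimator.
#'
#' @param I_b,J_b,I_x,I_y,K_by Square matrices in a common frame.
#' @param n Sample size the matrices were averaged over.
#' @param d Primary-block dimension (defaults to the frame size).
#' @param f Nuisance-block dimension.
#' @param eval_point Optional \code{"gmm_params"}.
#' @return An \code{"info_matrices"} object with \code{I_zy = I_x - I_y}.
#' @export
as_info_matrices <- function(I_b, J_b, I_x, I_y, K_by, n,
                             d = nrow(as.matrix(I_b)), f = 0L,
                             eval_point = NULL) {
  m <- lapply(list(I_b = I_b, J_b = J_b, I_x = I_x, I_y = I_y, K_by = K_by),
              as.matrix)
  structure(c(m, list(I_zy = m$I_x - m$I_y, eval_point = eval_point,
                      n = as.integer(n), d = as.integer(d),
                      f = as.integer(f))),
            class = "info_matrices")
}

new_criterion <- function(name, goodness, penalties, n, fit_ref = NULL) {
  structure(list(name = name, value = goodness + sum(unlist(penalties)),
                 goodness_term = goodness, penalty_terms = penalties,
                 n = n, fit_ref = fit_ref),
            class = "criterion_value")
}

#' @export
print.criterion_value <- function(x, ...) {
  cat(sprintf("%s = %.4f  (goodness %.4f + penalties %s)\n", x$name, x$value,
              x$goodness_term,
              paste(sprintf("%s=%.4f", names(x$penalty_terms),
                            unlist(x$penalty_terms)), collapse = ", ")))
  invisible(x)
}

#' Compute a criterion from an average log-likelihood and matrices
#'
#' Core arithmetic of the criteria family, taking the Y-marginal average
#' log-likelihood at the relevant MLE together with the empirical information
#' matrices.  The high-level wrappers (\code{\link{ic_risk_xb}} and friends)
#' delegate here; tests can call it directly with hand-built matrices.
#'
#' @param name One of \code{"RISKHAT_xb"}, \code{"AIC_xb"}, \code{"AIC_xy"},
#'   \code{"AIC_yb"}, \code{"AIC_yy"}, \code{"TIC"}.
#' @param elly Average Y-marginal log-likelihood at the evaluation point
#'   (\eqn{\ell_y(\hat\theta_b)} or \eqn{\ell_y(\hat\theta_y)}).
#' @param mats An \code{"info_matrices"} object (ignored for
#'   \code{"AIC_yy"}).
#' @param n Sample size; defaults to \code{mats$n}.
#' @param d Primary-block dimension for \code{"AIC_yy"}/\code{"AIC_xy"};
#'   defaults to \code{mats$d}.
#' @param fit_ref Optional fit stored on the result.
#' @return A \code{"criterion_value"}.
#' @export
criterion_from_matrices <- function(name, elly, mats = NULL,
                                    n = mats$n, d = mats$d, fit_ref = NULL) {
  goodness <- -2 * n * elly
  need_y_frame <- function() {
    if (!is.null(mats$f) && mats$f > 0L)
      stop(name, " requires matrices of a no-auxiliary fit (f = 0)")
  }
  pen <- switch(name,
    RISKHAT_xb = list(
      "2tr(Ib^-1 Kby)" = 2 * tr(solve(mats$I_b, mats$K_by)),
      "tr(Izy Ib^-1 Jb Ib^-1)" =
        tr(solve(mats$I_b, mats$J_b) %*% solve(mats$I_b, mats$I_zy))),
    AIC_xb = list(
      "tr(Ix Ib^-1)" = tr(solve(mats$I_b, mats$I_x)),
      "tr(Iy Ib^-1)" = tr(solve(mats$I_b, mats$I_y))),
    AIC_xy = {
      need_y_frame()
      list("tr(Ix Iy^-1)" = tr(solve(mats$I_y, mats$I_x)), d = d)
    },
    AIC_yb = list(
      "2tr(Iy Ib^-1)" = 2 * tr(solve(mats$I_b, mats$I_y))),
    AIC_yy = list("2d" = 2 * d),
    TIC = {
      need_y_frame()
      list("2tr(Iy^-1 Jy)" = 2 * tr(solve(mats$I_b, mats$J_b)))
    },
    stop("unknown criterion name: ", name))
  if (!all(is.finite(unlist(pen))))
    stop("non-finite penalty term in ", name)
  new_criterion(name, goodness, pen, n, fit_ref)
}

## average Y-marginal log-likelihood of a fit's theta-part on the data
elly_of <- function(fit, data) mean(logdensity_y(fit$params, data$y))

#' Information criteria for auxiliary-variable selection
#'
#' The criteria family estimating (twice) the Kullback-Leibler risk of the
#' plug-in predictive distribution of the complete primary data
#' \eqn{X = (Y, Z)}:
#' \describe{
#'   \item{\code{ic_risk_xb}}{the misspecification-robust criterion
#'     \eqn{-2n\ell_y(\hat\theta_b) + 2 tr(\hat I_b^{-1}\hat K_{b,y}) +
#'     tr(\hat I_{z|y}\hat I_b^{-1}\hat J_b\hat I_b^{-1})} for a fit that
#'     used the auxiliary variable; reduces to TIC when there is no latent
#'     part and no auxiliary variable.}
#'   \item{\code{ic_aic_xb}}{its correct-specification simplification
#'     \eqn{-2n\ell_y(\hat\theta_b) + tr(\hat I_x\hat I_b^{-1}) +
#'     tr(\hat I_y\hat I_b^{-1})}.}
#'   \item{\code{ic_aic_xy}}{the no-auxiliary counterpart
#'     \eqn{-2n\ell_y(\hat\theta_y) + tr(\hat I_x\hat I_y^{-1}) + d}.}
#'   \item{\code{ic_aic_yb}}{the complete-data (no latent part) criterion
#'     \eqn{-2n\ell_y(\hat\theta_b) + 2 tr(\hat I_y\hat I_b^{-1})} for
#'     auxiliary selection when predicting \eqn{Y} only.}
#'   \item{\code{ic_aic_yy}}{the classical AIC
#'     \eqn{-2n\ell_y(\hat\theta_y) + 2d}.}
#'   \item{\code{ic_tic}}{the classical TIC
#'     \eqn{-2n\ell_y(\hat\theta_y) + 2 tr(\hat I_y^{-1}\hat J_y)}.}
#' }
#' The goodness term always uses the Y-marginal average log-likelihood at the
#' fit's primary block (for a joint fit, the nuisance block is dropped, no
#' refit).
#'
#' @param fit A \code{"gmm_fit"}; joint (auxiliary) fit for the \code{*_xb} /
#'   \code{*_yb} criteria, y-only fit for the others.
#' @param mats The \code{\link{info_matrices}} evaluated at that same fit.
#' @param data The \code{"aux_dataset"} used for fitting.
#' @return A \code{"criterion_value"}.
#' @name criteria
NULL

check_pair <- function(fit, mats, data, want_aux) {
  stopifnot(inherits(fit, "gmm_fit"), inherits(mats, "info_matrices"),
            inherits(data, "aux_dataset"))
  if (want_aux && !fit$use_auxiliary)
    stop("this criterion requires a fit that used the auxiliary variable")
  if (!want_aux && fit$use_auxiliary)
    stop("this criterion requires a y-only fit")
}

#' @rdname criteria
#' @export
ic_risk_xb <- function(fit, mats, data) {
  check_pair(fit, mats, data, want_aux = TRUE)
  criterion_from_matrices("RISKHAT_xb", elly_of(fit, data), mats,
                          fit_ref = fit)
}

#' @rdname criteria
#' @export
ic_aic_xb <- function(fit, mats, data) {
  check_pair(fit, mats, data, want_aux = TRUE)
  criterion_from_matrices("AIC_xb", elly_of(fit, data), mats, fit_ref = fit)
}

#' @rdname criteria
#' @export
ic_aic_xy <- function(fit, mats, data) {
  check_pair(fit, mats, data, want_aux = FALSE)
  criterion_from_matrices("AIC_xy", elly_of(fit, data), mats, fit_ref = fit)
}

#' @rdname criteria
#' @export
ic_aic_yb <- function(fit, mats, data) {
  check_pair(fit, mats, data, want_aux = TRUE)
  criterion_from_matrices("AIC_yb", elly_of(fit, data), mats, fit_ref = fit)
}

#' @rdname criteria
#' @param d Parameter count of the primary block (4 for the mixture model).
#' @export
ic_aic_yy <- function(fit, data, d = 4L) {
  stopifnot(inherits(fit, "gmm_fit"))
  criterion_from_matrices("AIC_yy", elly_of(fit, data), mats = NULL,
                          n = data$n, d = d, fit_ref = fit)
}

#' @rdname criteria
#' @export
ic_tic <- function(fit, mats, data) {
  check_pair(fit, mats, data, want_aux = FALSE)
  criterion_from_matrices("TIC", elly_of(fit, data), mats, fit_ref = fit)
}

#' Select useful auxiliary variables by the criteria
#'
#' Fits the no-auxiliary model once and one joint model per candidate
#' auxiliary column, computes the relevant criterion pair, and declares a
#' candidate useful only when its criterion beats the no-auxiliary criterion
#' (for the x-target: \code{AIC_xb < AIC_xy}; for the y-target:
#' \code{AIC_yb < AIC_yy}).  The overall winner is the candidate with the
#' minimum criterion value; ties break toward the no-auxiliary model.
#' A candidate whose EM fit or information matrices fail is excluded (with a
#' warning), not fatal.
#'
#' @param df A data frame holding the primary and candidate columns.
#' @param primary Name of the primary column.
#' @param candidates Character vector of candidate auxiliary column names.
#' @param target \code{"x"} to target prediction of the complete primary data
#'   (latent label included), \code{"y"} for the observed part only.
#' @param control A \code{\link{fit_control}}.
#' @param seed Optional integer seed for the EM restarts.
#' @return An object of class \code{"selection_result"}: list with
#'   \code{candidates} (data frame of labels, criterion names, values,
#'   failure flags), \code{best_label} (\code{"<none>"} for the no-auxiliary
#'   model), \code{decision_rule}, and \code{fits}.
#' @export
select_auxiliary <- function(df, primary = "y", candidates,
                             target = c("x", "y"),
                             control = fit_control(), seed = NULL) {
  target <- match.arg(target)
  if (!primary %in% names(df)) stop("primary column '", primary, "' missing")
  missing_cols <- setdiff(candidates, names(df))
  if (length(missing_cols))
    stop("candidate column(s) not found: ", paste(missing_cols, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  base_data <- aux_dataset(y = df[[primary]])
  fit_y <- fit_gmm(base_data, use_auxiliary = FALSE, control = control)
  mats_y <- info_matrices(fit_y, base_data)
  base_crit <- if (target == "x") ic_aic_xy(fit_y, mats_y, base_data)
               else ic_aic_yy(fit_y, base_data)

  rows <- data.frame(label = "<none>", criterion = base_crit$name,
                     value = base_crit$value, failed = FALSE,
                     stringsAsFactors = FALSE)
  fits <- list(`<none>` = fit_y)
  for (lab in candidates) {
    cand <- tryCatch({
      d <- aux_dataset(y = df[[primary]], a = df[[lab]])
      fit_b <- fit_gmm(d, use_auxiliary = TRUE, control = control)
      mats_b <- info_matrices(fit_b, d)
      cr <- if (target == "x") ic_aic_xb(fit_b, mats_b, d)
            else ic_aic_yb(fit_b, mats_b, d)
      list(fit = fit_b,
           row = data.frame(label = lab, criterion = cr$name,
                            value = cr$value, failed = FALSE,
                            stringsAsFactors = FALSE))
    }, error = function(e) {
      warning("candidate '", lab, "' excluded: ", conditionMessage(e),
              call. = FALSE)
      list(fit = NULL,
           row = data.frame(label = lab, criterion = NA_character_,
                            value = NA_real_, failed = TRUE,
                            stringsAsFactors = FALSE))
    })
    if (!is.null(cand$fit)) fits[[lab]] <- cand$fit
    rows <- rbind(rows, cand$row)
  }
  ok <- rows[!rows$failed, ]
  ## ties break toward the no-auxiliary model, which sorts first
  ok <- ok[order(ok$label != "<none>"), ]
  best <- ok$label[which.min(ok$value)]
  structure(list(candidates = rows, best_label = best,
                 decision_rule = sprintf(
                   "%s: candidate useful iff %s < %s; argmin wins, ties to <none>",
                   target,
                   if (target == "x") "AIC_xb" else "AIC_yb",
                   if (target == "x") "AIC_xy" else "AIC_yy"),
                 target = target, fits = fits),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Auxiliary-variable selection (target:", x$target, ")\n")
  print(x$candidates, row.names = FALSE)
  cat("best:", x$best_label, "\n")
  invisible(x)
}
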