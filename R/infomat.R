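#' Empirical information matrices of a fitted candidate model
#'
#' Estimates, at the maximum likelihood estimate of a fit, the six matrices
#' entering the information criteria, all in the common p x p frame of the
#' flattened parameter vector (p = 8 with an auxiliary variable, p = 4
#' without):
#' \describe{
#'   \item{I_b}{minus the average Hessian of the observable-data
#'     log-likelihood (sandwich "bread").}
#'   \item{J_b}{average outer product of the observable-data scores
#'     (sandwich "meat"); equals \code{I_b} in expectation under correct
#'     specification.}
#'   \item{I_y}{minus the average Hessian of the Y-marginal log-likelihood,
#'     zero-padded over the nuisance block.}
#'   \item{I_x}{minus the average posterior-weighted Hessian of the
#'     complete-data log-likelihood; the latent expectation is taken under
#'     the fitted posterior \eqn{p_{z|y}(z | y_i; \hat\theta)}, which is the
#'     plug-in for the correct-latent-conditional assumption.}
#'   \item{I_zy}{\code{I_x - I_y}, the information of the latent part given
#'     the observed part; positive semidefinite on the primary block.}
#'   \item{K_by}{average cross product of observable-data and Y-marginal
#'     scores.}
#' }
#'
#' @param fit A \code{"gmm_fit"} from \code{\link{fit_gmm}}.
#' @param data The \code{"aux_dataset"} the fit was computed on.
#' @param use_auxiliary Whether the fit used the auxiliary variable
#'   (defaults to the fit's own flag).
#' @param latent Set \code{FALSE} to collapse the latent part (the
#'   "X = Y" reduction): \code{I_x} is then set equal to \code{I_y}, so the
#'   criteria built from the result reduce to their complete-data forms.
#' @param max_condition Error when the condition number of \code{I_b}
#'   exceeds this (a near-singular information matrix invalidates the
#'   criteria).
#' @return An object of class \code{"info_matrices"}: list with the six
#'   matrices, \code{eval_point} (the MLE), \code{n}, \code{d}, \code{f}.
#' @export
info_matrices <- function(fit, data, use_auxiliary = fit$use_auxiliary,
                          latent = TRUE, max_condition = 1e12) {
  stopifnot(inherits(fit, "gmm_fit"), inherits(data, "aux_dataset"))
  params <- fit$params
  if (use_auxiliary && !has_aux(params))
    stop("use_auxiliary = TRUE but the fit has no auxiliary block")
  y <- data$y
  a <- if (use_auxiliary) data$a else NULL
  n <- data$n
  frame <- length(flatten_params(params))
  kind_b <- if (use_auxiliary) "b" else "y"

  sc_b <- grad_loglik(kind_b, params, y, a)
  J_b <- crossprod(sc_b) / n
  I_b <- -hess_avg_loglik(kind_b, params, y, a)

  kap <- kappa(I_b, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stop(sprintf(paste0("information matrix I_b is numerically singular ",
                        "(condition number %.3g > %.3g)"), kap, max_condition))

  I_y <- -hess_avg_loglik("y", params, y)
  if (latent) {
    w1 <- posterior_z(params, y)[, 1L]
    I_x <- -hess_avg_loglik("x-weighted", params, y, weights = w1)
  } else {
    I_x <- I_y
  }
  I_zy <- I_x - I_y
  sc_y <- grad_loglik("y", params, y)
  K_by <- crossprod(sc_b, sc_y) / n

  structure(list(I_b = I_b, J_b = J_b, I_x = I_x, I_y = I_y, I_zy = I_zy,
                 K_by = K_by, eval_point = params, n = n,
                 d = 4L, f = frame - 4L),
            class = "info_matrices")
}

#' @export
print.info_matrices <- function(x, ...) {
  cat(sprintf("Empirical information matrices (%d x %d frame, n = %d)\n",
              x$d + x$f, x$d + x$f, x$n))
  cat(sprintf("  tr(I_b^-1 J_b) = %.4f  tr(I_zy I_b^-1) = %.4f\n",
              sum(diag(solve(x$I_b, x$J_b))),
              sum(diag(solve(x$I_b, x$I_zy)))))
  invisible(x)
}

#' Export information matrices to delimited text
#'
#' Writes each matrix as a labelled CSV (rows/columns in the documented
#' flattening order) into a directory, for external inspection.
#'
#' @param mats An \code{"info_matrices"} object.
#' @param out_dir Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_info_matrices <- function(mats, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  nm <- c("I_b", "J_b", "I_x", "I_y", "I_zy", "K_by")
  paths <- character(0)
  for (m in nm) {
    p <- file.path(out_dir, paste0(m, ".csv"))
    utils::write.csv(mats[[m]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
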