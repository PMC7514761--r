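#' Parameters of the two-component Gaussian mixture candidate model
#'
#' Container for the parameter vector \eqn{\beta = (\theta, \phi)} of the
#' two-component mixture used as the candidate model throughout the package.
#' The primary block \eqn{\theta = (\pi_1, \mu_{1y}, \mu_{2y}, \sigma_y^2)}
#' describes the mixture over the observed primary variable \eqn{Y} with a
#' latent component label \eqn{Z \in \{0, 1\}} (component 1 corresponds to
#' \eqn{Z = 1}) and a variance shared across components.  The optional
#' nuisance block \eqn{\phi = (\mu_{1a}, \mu_{2a}, \sigma_a^2, \sigma_{ya})}
#' extends the model to the joint distribution of \eqn{(Y, A)} with a single
#' auxiliary variable \eqn{A} and a shared 2x2 covariance matrix
#' \eqn{\Sigma = [[\sigma_y^2, \sigma_{ya}], [\sigma_{ya}, \sigma_a^2]]}.
#'
#' The flattening order used by every vector/matrix interface in the package
#' is fixed: \code{(pi1, mu1y, mu2y, sigma_y2)} followed, when the auxiliary
#' block is present, by \code{(mu1a, mu2a, sigma_a2, sigma_ya)}; hence
#' \eqn{d = 4} primary parameters and \eqn{f = 4} (or \eqn{f = 0}) nuisance
#' parameters.
#'
#' @param pi1 Mixing weight of component 1 (the \eqn{Z = 1} component),
#'   strictly inside (0, 1).
#' @param mu1y,mu2y Component means of \eqn{Y}.
#' @param sigma_y2 Shared variance of \eqn{Y}, positive.
#' @param mu1a,mu2a Component means of \eqn{A}, or \code{NULL} for a model
#'   without auxiliary variable.
#' @param sigma_a2 Shared variance of \eqn{A}, positive when present.
#' @param sigma_ya Shared covariance of \eqn{(Y, A)} when present.
#'
#' @return An object of class \code{"gmm_params"}.
#' @examples
#' th <- gmm_params(0.6, -1.2, 1.2, 0.7)
#' be <- gmm_params(0.6, -1.2, 1.2, 0.7, 1.8, -1.8, 0.49, 0)
#' has_aux(be)
#' as.numeric(flatten_params(be))
#' @export
gmm_params <- function(pi1, mu1y, mu2y, sigma_y2,
                       mu1a = NULL, mu2a = NULL,
                       sigma_a2 = NULL, sigma_ya = NULL) {
  aux_fields <- list(mu1a, mu2a, sigma_a2, sigma_ya)
  n_aux <- sum(!vapply(aux_fields, is.null, logical(1)))
  if (n_aux != 0L && n_aux != 4L)
    stop("auxiliary fields mu1a, mu2a, sigma_a2, sigma_ya must be given together")
  p <- structure(
    list(pi1 = as.numeric(pi1), mu1y = as.numeric(mu1y),
         mu2y = as.numeric(mu2y), sigma_y2 = as.numeric(sigma_y2),
         mu1a = if (n_aux) as.numeric(mu1a), mu2a = if (n_aux) as.numeric(mu2a),
         sigma_a2 = if (n_aux) as.numeric(sigma_a2),
         sigma_ya = if (n_aux) as.numeric(sigma_ya)),
    class = "gmm_params")
  validate_params(p)
  p
}

#' @rdname gmm_params
#' @param params A \code{"gmm_params"} object.
#' @export
has_aux <- function(params) !is.null(params$mu1a)

validate_params <- function(params) {
  with(params, {
    if (!is.finite(pi1) || pi1 <= 0 || pi1 >= 1)
      stop("pi1 must lie strictly in (0, 1)")
    if (!is.finite(sigma_y2) || sigma_y2 <= 0)
      stop("sigma_y2 must be positive")
    if (!is.finite(mu1y) || !is.finite(mu2y))
      stop("component means must be finite")
  })
  if (has_aux(params)) {
    S <- cov_matrix(params)
    # positive definiteness of the shared 2x2 covariance
    if (params$sigma_a2 <= 0 || det(S) <= 0)
      stop("covariance matrix [[sigma_y2, sigma_ya], [sigma_ya, sigma_a2]] ",
           "must be positive definite")
  }
  invisible(params)
}

cov_matrix <- function(params) {
  matrix(c(params$sigma_y2, params$sigma_ya,
           params$sigma_ya, params$sigma_a2), 2L, 2L)
}

#' @rdname gmm_params
#' @export
flatten_params <- function(params) {
  v <- c(pi1 = params$pi1, mu1y = params$mu1y, mu2y = params$mu2y,
         sigma_y2 = params$sigma_y2)
  if (has_aux(params))
    v <- c(v, mu1a = params$mu1a, mu2a = params$mu2a,
           sigma_a2 = params$sigma_a2, sigma_ya = params$sigma_ya)
  v
}

#' @rdname gmm_params
#' @param beta Numeric vector of length 4 or 8 in the documented flattening
#'   order.
#' @param validate Check parameter-space constraints (set \code{FALSE} inside
#'   finite-difference loops that may probe slightly infeasible points).
#' @export
unflatten_params <- function(beta, validate = TRUE) {
  stopifnot(length(beta) %in% c(4L, 8L))
  p <- if (length(beta) == 4L)
    list(pi1 = beta[[1L]], mu1y = beta[[2L]], mu2y = beta[[3L]],
         sigma_y2 = beta[[4L]], mu1a = NULL, mu2a = NULL,
         sigma_a2 = NULL, sigma_ya = NULL)
  else
    list(pi1 = beta[[1L]], mu1y = beta[[2L]], mu2y = beta[[3L]],
         sigma_y2 = beta[[4L]], mu1a = beta[[5L]], mu2a = beta[[6L]],
         sigma_a2 = beta[[7L]], sigma_ya = beta[[8L]])
  p <- structure(p, class = "gmm_params")
  if (validate) validate_params(p)
  p
}

#' Drop the auxiliary block of a parameter vector
#'
#' Returns the primary block \eqn{\theta} of \eqn{\beta = (\theta, \phi)} as a
#' stand-alone y-only model, as used when evaluating the Y-marginal
#' log-likelihood of a joint fit.
#'
#' @param params A \code{"gmm_params"} object.
#' @return A \code{"gmm_params"} object without auxiliary fields.
#' @export
theta_part <- function(params) {
  gmm_params(params$pi1, params$mu1y, params$mu2y, params$sigma_y2)
}

#' Swap mixture component labels
#'
#' Applies the label swap \eqn{(\pi_1, \mu_1, \mu_2) \to
#' (1 - \pi_1, \mu_2, \mu_1)}, which leaves every observable-data density
#' unchanged.  Used when aligning an estimate to a reference labelling before
#' evaluating the complete-data loss.
#'
#' @param params A \code{"gmm_params"} object.
#' @return The label-swapped \code{"gmm_params"}.
#' @export
swap_components <- function(params) {
  if (has_aux(params))
    gmm_params(1 - params$pi1, params$mu2y, params$mu1y, params$sigma_y2,
               params$mu2a, params$mu1a, params$sigma_a2, params$sigma_ya)
  else
    gmm_params(1 - params$pi1, params$mu2y, params$mu1y, params$sigma_y2)
}

#' Align mixture component labels to a reference
#'
#' Returns \code{params} or its component swap, whichever has the primary
#' block (\eqn{\theta}) closer to \code{reference} in Euclidean distance.
#' Mixture labels are arbitrary; any quantity that refers to a specific
#' labelling (complete-data losses, cross-entropies against a reference
#' posterior) must be computed after alignment.
#'
#' @param params A \code{"gmm_params"} object.
#' @param reference A \code{"gmm_params"} providing the target labelling.
#' @return \code{params}, possibly label-swapped.
#' @export
align_components <- function(params, reference) {
  th <- flatten_params(params)[1:4]
  ref <- flatten_params(reference)[1:4]
  sw <- flatten_params(swap_components(params))[1:4]
  if (sum((sw - ref)^2) < sum((th - ref)^2)) swap_components(params) else params
}

#' @export
print.gmm_params <- function(x, digits = 4L, ...) {
  cat("Two-component GMM parameters",
      if (has_aux(x)) "(with auxiliary variable)" else "(y-only)", "\n")
  print(round(flatten_params(x), digits))
  invisible(x)
}
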