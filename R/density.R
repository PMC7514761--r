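## Log-density kernels of the candidate model.  Everything is vectorized over
## observations; two-term mixtures are combined with logsumexp for stability.

logsumexp2 <- function(l1, l2) {
  m <- pmax(l1, l2)
  m[!is.finite(m)] <- 0  # both -Inf: result -Inf via log(0)
  m + log(exp(l1 - m) + exp(l2 - m))
}

## log N(y; mu, sigma2), vectorized
log_dnorm <- function(y, mu, sigma2) {
  dnorm(y, mean = mu, sd = sqrt(sigma2), log = TRUE)
}

## log N2((y,a); mu, Sigma) with Sigma = [[sy, sya], [sya, sa]]
log_dbnorm <- function(y, a, muy, mua, sy, sa, sya) {
  det_s <- sy * sa - sya * sya
  dy <- y - muy
  da <- a - mua
  q <- (sa * dy * dy - 2 * sya * dy * da + sy * da * da) / det_s
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

## per-component log densities of the joint model, n x 2 matrix
logcomp_b <- function(params, y, a) {
  cbind(log_dbnorm(y, a, params$mu1y, params$mu1a,
                   params$sigma_y2, params$sigma_a2, params$sigma_ya),
        log_dbnorm(y, a, params$mu2y, params$mu2a,
                   params$sigma_y2, params$sigma_a2, params$sigma_ya))
}

logcomp_y <- function(params, y) {
  cbind(log_dnorm(y, params$mu1y, params$sigma_y2),
        log_dnorm(y, params$mu2y, params$sigma_y2))
}

#' Log-density of the observable joint model
#'
#' Evaluates \eqn{\log p_b(y, a; \beta) = \log[\pi_1 N_2((y,a); \mu_1, \Sigma)
#' + (1 - \pi_1) N_2((y,a); \mu_2, \Sigma)]}, the marginal (over the latent
#' label) density of the two-component bivariate mixture.
#'
#' @param params A \code{"gmm_params"} object with auxiliary fields.
#' @param y,a Numeric vectors of equal length.
#' @return Numeric vector of log-densities.
#' @export
logdensity_joint <- function(params, y, a) {
  if (!has_aux(params)) stop("params carry no auxiliary block")
  validate_params(params)
  lc <- logcomp_b(params, y, a)
  logsumexp2(log(params$pi1) + lc[, 1L], log1p(-params$pi1) + lc[, 2L])
}

#' Log-density of the observed primary variable
#'
#' Evaluates \eqn{\log p_y(y; \theta) = \log[\pi_1 N(y; \mu_{1y}, \sigma_y^2)
#' + (1 - \pi_1) N(y; \mu_{2y}, \sigma_y^2)]}.  Only the primary block of
#' \code{params} is used; auxiliary fields, if present, are ignored.
#'
#' @param params A \code{"gmm_params"} object.
#' @param y Numeric vector.
#' @return Numeric vector of log-densities.
#' @export
logdensity_y <- function(params, y) {
  if (params$sigma_y2 <= 0) stop("sigma_y2 must be positive")
  lc <- logcomp_y(params, y)
  logsumexp2(log(params$pi1) + lc[, 1L], log1p(-params$pi1) + lc[, 2L])
}

#' Log-density of the complete primary data
#'
#' Evaluates \eqn{\log p_x(y, z; \theta) = z[\log \pi_1 +
#' \log N(y; \mu_{1y}, \sigma_y^2)] + (1-z)[\log(1-\pi_1) +
#' \log N(y; \mu_{2y}, \sigma_y^2)]} for binary labels \eqn{z}.
#'
#' @param params A \code{"gmm_params"} object.
#' @param y Numeric vector.
#' @param z Binary vector (0/1) of the same length.
#' @return Numeric vector of log-densities.
#' @export
logdensity_x <- function(params, y, z) {
  if (params$sigma_y2 <= 0) stop("sigma_y2 must be positive")
  if (!all(z %in% c(0, 1))) stop("z must contain only 0 or 1")
  lc <- logcomp_y(params, y)
  z * (log(params$pi1) + lc[, 1L]) + (1 - z) * (log1p(-params$pi1) + lc[, 2L])
}

#' Posterior probability of the latent label
#'
#' Returns the posterior distribution of \eqn{Z} given the observation: given
#' \eqn{y} only when \code{a} is absent (\eqn{p_{z|y}(z | y; \theta)}), and
#' given \eqn{(y, a)} when \code{a} is supplied
#' (\eqn{p_{z|b}(z | y, a; \beta)}).
#'
#' @param params A \code{"gmm_params"} object (with auxiliary fields when
#'   \code{a} is given).
#' @param y Numeric vector.
#' @param a Optional numeric vector of the same length.
#' @return An n x 2 matrix with columns \code{z1} (probability of \eqn{Z=1})
#'   and \code{z0}, each row summing to 1.
#' @export
posterior_z <- function(params, y, a = NULL) {
  lc <- if (is.null(a)) logcomp_y(params, y) else {
    if (!has_aux(params)) stop("params carry no auxiliary block")
    logcomp_b(params, y, a)
  }
  l1 <- log(params$pi1) + lc[, 1L]
  l2 <- log1p(-params$pi1) + lc[, 2L]
  g <- 1 / (1 + exp(l2 - l1))
  cbind(z1 = g, z0 = 1 - g)
}
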