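#' The true generative model of the simulation study
#'
#' Constants of the two-component Gaussian data-generating process used
#' throughout the simulation experiments.  The primary pair is generated as
#' \eqn{Z \sim Bernoulli(0.6)}, \eqn{Y | Z = 1 \sim N(-1.2, 0.7)},
#' \eqn{Y | Z = 0 \sim N(1.2, 0.7)}.  The auxiliary variable is
#' \eqn{A | Z = 1 \sim N(1.8, 0.49)}, \eqn{A | Z = 0 \sim N(-1.8, 0.49)} in
#' Case 1 (informative: the candidate joint model is correctly specified),
#' while in Case 2 \eqn{A} is drawn from the same 0.6/0.4 mixture
#' independently of \eqn{(Y, Z)} (pure noise: the joint model is
#' misspecified).
#'
#' @param case_id \code{"case1"} or \code{"case2"}.
#' @return A list of class \code{"true_model"} with elements \code{case_id},
#'   \code{theta0} (\code{"gmm_params"}, y-only true primary block),
#'   \code{beta0} (full \code{"gmm_params"}; the Case 1 truth),
#'   \code{pi1}, \code{mu_y}, \code{var_y}, \code{mu_a}, \code{var_a}.
#' @export
true_model <- function(case_id = c("case1", "case2")) {
  case_id <- match.arg(case_id)
  structure(list(
    case_id = case_id,
    pi1 = 0.6,
    mu_y = c(-1.2, 1.2), var_y = 0.7,
    mu_a = c(1.8, -1.8), var_a = 0.49,
    theta0 = gmm_params(0.6, -1.2, 1.2, 0.7),
    beta0 = gmm_params(0.6, -1.2, 1.2, 0.7, 1.8, -1.8, 0.49, 0)),
    class = "true_model")
}

## -E_{q_{y|z=k}}[ log N(y; mu, s2) ] terms assembled by quadrature
loss_x_unaligned <- function(params, rule) {
  tm <- true_model()
  e1 <- gh_expect(function(y) log_dnorm(y, params$mu1y, params$sigma_y2),
                  tm$mu_y[1L], tm$var_y, rule)
  e0 <- gh_expect(function(y) log_dnorm(y, params$mu2y, params$sigma_y2),
                  tm$mu_y[2L], tm$var_y, rule)
  -(tm$pi1 * (log(params$pi1) + e1) +
    (1 - tm$pi1) * (log1p(-params$pi1) + e0))
}

#' True complete-data and observed-data losses
#'
#' \code{true_loss_x} evaluates the complete-data loss
#' \eqn{L_x(\theta) = -\sum_z q_z(z)\int q_{y|z}(y|z) \log p_x(y,z;\theta) dy}
#' of the candidate primary model against the true generative process, by
#' Gauss-Hermite quadrature (one rule per true component).  Because the
#' mixture labels are not identified, the value returned is the minimum over
#' the two label assignments (the estimate and its component swap); pass
#' \code{align = FALSE} for the raw single-assignment value.
#' \code{true_loss_y} evaluates the observed-data loss
#' \eqn{L_y(\theta) = -\int q_y(y) \log p_y(y;\theta) dy}; no alignment is
#' needed because \eqn{p_y} is label-symmetric.
#'
#' @param params A \code{"gmm_params"} (only the primary block is used).
#' @param nodes Number of quadrature nodes per component.
#' @param align Minimize over the two component-label assignments.
#' @param rule Optional precomputed \code{\link{gauss_hermite}} rule.
#' @return The loss value (negative expected log-density under the truth).
#' @export
true_loss_x <- function(params, nodes = 64L, align = TRUE, rule = NULL) {
  if (params$sigma_y2 <= 0) stop("sigma_y2 must be positive")
  if (is.null(rule)) rule <- gauss_hermite(nodes)
  v <- loss_x_unaligned(params, rule)
  if (align)
    v <- min(v, loss_x_unaligned(swap_components(params), rule))
  if (!is.finite(v)) stop("loss quadrature is non-finite")
  v
}

#' @rdname true_loss_x
#' @export
true_loss_y <- function(params, nodes = 64L, rule = NULL) {
  if (params$sigma_y2 <= 0) stop("sigma_y2 must be positive")
  if (is.null(rule)) rule <- gauss_hermite(nodes)
  tm <- true_model()
  f <- function(y) logdensity_y(params, y)
  v <- -(tm$pi1 * gh_expect(f, tm$mu_y[1L], tm$var_y, rule) +
         (1 - tm$pi1) * gh_expect(f, tm$mu_y[2L], tm$var_y, rule))
  if (!is.finite(v)) stop("loss quadrature is non-finite")
  v
}
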