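## Derivative engine for the empirical information matrices.
##
## Analytic per-observation score vectors are the fast path; central finite
## differences are the reference path, and the two must agree (tested).
## All gradients live in the flattening order of gmm_params:
## (pi1, mu1y, mu2y, sigma_y2[, mu1a, mu2a, sigma_a2, sigma_ya]).

## analytic scores of log pb(y, a; beta), n x 8
score_b_analytic <- function(params, y, a) {
  g <- posterior_z(params, y, a)[, 1L]
  sy <- params$sigma_y2; sa <- params$sigma_a2; sya <- params$sigma_ya
  dt <- sy * sa - sya * sya
  iyy <- sa / dt; iaa <- sy / dt; iya <- -sya / dt
  d1y <- y - params$mu1y; d1a <- a - params$mu1a
  d2y <- y - params$mu2y; d2a <- a - params$mu2a
  u1y <- iyy * d1y + iya * d1a; u1a <- iya * d1y + iaa * d1a
  u2y <- iyy * d2y + iya * d2a; u2a <- iya * d2y + iaa * d2a
  w2 <- 1 - g
  cbind(pi1 = g / params$pi1 - w2 / (1 - params$pi1),
        mu1y = g * u1y,
        mu2y = w2 * u2y,
        sigma_y2 = 0.5 * (g * (u1y^2 - iyy) + w2 * (u2y^2 - iyy)),
        mu1a = g * u1a,
        mu2a = w2 * u2a,
        sigma_a2 = 0.5 * (g * (u1a^2 - iaa) + w2 * (u2a^2 - iaa)),
        sigma_ya = g * (u1y * u1a - iya) + w2 * (u2y * u2a - iya))
}

## analytic scores of log py(y; theta), n x 4 (theta block only)
score_y_analytic <- function(params, y) {
  g <- posterior_z(params, y)[, 1L]
  s2 <- params$sigma_y2
  d1 <- y - params$mu1y; d2 <- y - params$mu2y
  w2 <- 1 - g
  cbind(pi1 = g / params$pi1 - w2 / (1 - params$pi1),
        mu1y = g * d1 / s2,
        mu2y = w2 * d2 / s2,
        sigma_y2 = 0.5 * (g * (d1^2 / s2^2 - 1 / s2) +
                          w2 * (d2^2 / s2^2 - 1 / s2)))
}

## analytic scores of the posterior-weighted complete-data log-density
## sum_z w(z|y) * grad log px(y, z; theta); weights w1 fixed by the caller
score_x_weighted_analytic <- function(params, y, w1) {
  s2 <- params$sigma_y2
  d1 <- y - params$mu1y; d2 <- y - params$mu2y
  w0 <- 1 - w1
  cbind(pi1 = w1 / params$pi1 - w0 / (1 - params$pi1),
        mu1y = w1 * d1 / s2,
        mu2y = w0 * d2 / s2,
        sigma_y2 = 0.5 * (w1 * (d1^2 / s2^2 - 1 / s2) +
                          w0 * (d2^2 / s2^2 - 1 / s2)))
}

## is a flattened beta a valid interior point of the parameter space?
beta_feasible <- function(beta) {
  ok <- beta[1L] > 0 && beta[1L] < 1 && beta[4L] > 0
  if (ok && length(beta) == 8L)
    ok <- beta[7L] > 0 && (beta[4L] * beta[7L] - beta[8L]^2) > 0
  ok
}

## boundary-aware central-difference step for coordinate j
fd_step <- function(beta, j) {
  h <- .Machine$double.eps^(1/3) * max(1, abs(beta[j]))
  for (k in 0:60) {
    bp <- beta; bm <- beta
    bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
    if (beta_feasible(bp) && beta_feasible(bm)) return(h)
    h <- h / 2
  }
  stop("cannot take a finite-difference step at the parameter-space boundary",
       " (coordinate ", j, ")")
}

## evaluate the n-vector of log densities at a flattened beta
logdens_at <- function(kind, beta, y, a, w1) {
  p <- unflatten_params(beta, validate = FALSE)
  switch(kind,
    b = {
      lc <- logcomp_b(p, y, a)
      logsumexp2(log(p$pi1) + lc[, 1L], log1p(-p$pi1) + lc[, 2L])
    },
    y = {
      lc <- logcomp_y(p, y)
      logsumexp2(log(p$pi1) + lc[, 1L], log1p(-p$pi1) + lc[, 2L])
    },
    `x-weighted` = {
      lc <- logcomp_y(p, y)
      w1 * (log(p$pi1) + lc[, 1L]) + (1 - w1) * (log1p(-p$pi1) + lc[, 2L])
    },
    stop("unknown density kind: ", kind))
}

## which coordinates of the frame does each density kind actually use
active_coords <- function(kind, frame) {
  if (kind == "b") seq_len(frame) else 1:4
}

#' Per-observation score vectors of the model log-densities
#'
#' Computes the gradient of the chosen log-density with respect to the full
#' flattened parameter vector, one row per observation.  Coordinates the
#' density does not depend on (the nuisance block for kinds \code{"y"} and
#' \code{"x-weighted"}) are exactly zero.  Kind \code{"x-weighted"} is the
#' posterior-weighted complete-data score \eqn{\sum_z w(z|y_i)
#' \nabla \log p_x(y_i, z; \theta)} used for the latent-part information
#' matrix; \code{weights} defaults to the marginal posterior
#' \eqn{p_{z|y}(1|y_i; \theta)} at \code{params}.
#'
#' @param kind One of \code{"b"}, \code{"y"}, \code{"x-weighted"}.
#' @param params A \code{"gmm_params"} object (auxiliary fields required for
#'   kind \code{"b"}).
#' @param y Numeric vector of observations.
#' @param a Auxiliary values (kind \code{"b"} only).
#' @param weights Optional vector of latent-class-1 weights for
#'   \code{"x-weighted"}.
#' @param method \code{"analytic"} (default) or \code{"numeric"} (central
#'   finite differences with boundary-aware steps).
#' @return An n x p score matrix, p = 4 or 8 following \code{params}.
#' @export
grad_loglik <- function(kind = c("b", "y", "x-weighted"), params, y, a = NULL,
                        weights = NULL, method = c("analytic", "numeric")) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  validate_params(params)
  if (kind == "b") {
    if (!has_aux(params)) stop("kind 'b' requires auxiliary parameters")
    if (is.null(a)) stop("kind 'b' requires auxiliary observations")
  }
  if (kind == "x-weighted" && is.null(weights))
    weights <- posterior_z(params, y)[, 1L]
  beta <- flatten_params(params)
  frame <- length(beta)
  if (method == "analytic") {
    sc <- switch(kind,
      b = score_b_analytic(params, y, a),
      y = score_y_analytic(params, y),
      `x-weighted` = score_x_weighted_analytic(params, y, weights))
    if (ncol(sc) < frame)
      sc <- cbind(sc, matrix(0, nrow(sc), frame - ncol(sc),
                             dimnames = list(NULL, names(beta)[5:8])))
    return(sc)
  }
  out <- matrix(0, length(y), frame, dimnames = list(NULL, names(beta)))
  for (j in active_coords(kind, frame)) {
    h <- fd_step(beta, j)
    bp <- beta; bm <- beta
    bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
    out[, j] <- (logdens_at(kind, bp, y, a, weights) -
                 logdens_at(kind, bm, y, a, weights)) / (2 * h)
  }
  out
}

## Hessian of the sample-average log-density, by central differences of the
## analytic average score; symmetrized.  p x p in the frame of `params`.
hess_avg_loglik <- function(kind, params, y, a = NULL, weights = NULL) {
  if (kind == "x-weighted" && is.null(weights))
    weights <- posterior_z(params, y)[, 1L]
  beta <- flatten_params(params)
  frame <- length(beta)
  avg_grad <- function(b) {
    p <- unflatten_params(b, validate = FALSE)
    sc <- switch(kind,
      b = score_b_analytic(p, y, a),
      y = score_y_analytic(p, y),
      `x-weighted` = score_x_weighted_analytic(p, y, weights))
    colMeans(sc)
  }
  act <- active_coords(kind, frame)
  H <- matrix(0, frame, frame, dimnames = list(names(beta), names(beta)))
  for (j in act) {
    h <- fd_step(beta, j)
    bp <- beta; bm <- beta
    bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
    H[act, j] <- (avg_grad(bp) - avg_grad(bm)) / (2 * h)
  }
  (H + t(H)) / 2
}
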