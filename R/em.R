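#' Fitting configuration for the EM estimator
#'
#' @param tol Convergence tolerance on the relative change of the average
#'   log-likelihood between EM iterations.
#' @param max_iter Maximum number of EM iterations per restart.
#' @param n_restarts Number of EM restarts.  Restart 1 starts from data-driven
#'   moments (split at the median of y); for joint fits restart 2 splits at
#'   the median of a (so both clustering axes seed a basin); further restarts
#'   perturb the y-split moments using the current RNG stream.  The best
#'   final log-likelihood wins.  Mixture likelihoods are multimodal, so
#'   several restarts are the safe default.
#' @param variance_floor Lower bound on the eigenvalues of the fitted
#'   covariance; a restart whose covariance falls below the floor is
#'   discarded as degenerate (the mixture likelihood is unbounded).
#' @param min_count Minimum expected number of observations per component,
#'   \eqn{n \min(\hat\pi_1, 1 - \hat\pi_1)}, for a converged restart to be
#'   accepted.  Local maximizers that park a vanishing-weight component on
#'   one or two extreme points are spurious in the mixture-model sense: they
#'   can beat the interior maximizer's likelihood at small n while being
#'   statistically meaningless, and they wreck the plug-in predictive
#'   distribution.  Such restarts are discarded like degenerate ones.
#' @param min_separation Minimum Mahalanobis distance between the two
#'   component means (with respect to the shared covariance) for a converged
#'   restart to be accepted.  A solution with essentially coincident
#'   components has collapsed onto the single-Gaussian submodel, where the
#'   mixture parameters are unidentified and the information matrices
#'   backing the criteria are singular; such ridge solutions are spurious
#'   for the same reason as vanishing-weight ones.
#' @param seed Optional integer seed; \code{NULL} uses the current RNG
#'   stream (so that callers managing replicate substreams stay in control).
#' @return A list of class \code{"fit_control"}.
#' @export
fit_control <- function(tol = 1e-10, max_iter = 2000L, n_restarts = 5L,
                        variance_floor = 1e-8, min_count = 2,
                        min_separation = 0.1, seed = NULL) {
  stopifnot(tol > 0, max_iter >= 1L, n_restarts >= 1L, variance_floor > 0,
            min_count >= 0, min_separation >= 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts),
                 variance_floor = variance_floor, min_count = min_count,
                 min_separation = min_separation, seed = seed),
            class = "fit_control")
}

## Moment-based starting values: split the sample at the median of one
## observed coordinate (y, or a for joint fits — the two structured starts
## cover both clustering axes), per-half means, pooled variance.
## `jitter = TRUE` perturbs the moments for the remaining restarts.
em_start <- function(y, a, split_on = c("y", "a"), jitter = FALSE) {
  split_on <- match.arg(split_on)
  sv <- if (split_on == "a") a else y
  med <- stats::median(sv)
  lo <- sv <= med
  if (all(lo) || !any(lo)) lo <- seq_along(y) <= length(y) / 2
  m1y <- mean(y[lo]); m2y <- mean(y[!lo])
  vy <- (sum((y[lo] - m1y)^2) + sum((y[!lo] - m2y)^2)) / length(y)
  vy <- max(vy, 1e-4 * stats::var(y), 1e-8)
  pi1 <- 0.5
  if (jitter) {
    sy <- stats::sd(y)
    pi1 <- stats::runif(1, 0.2, 0.8)
    m1y <- m1y + stats::rnorm(1, sd = sy)
    m2y <- m2y + stats::rnorm(1, sd = sy)
    vy <- vy * exp(stats::runif(1, -0.7, 0.7))
  }
  if (is.null(a))
    return(gmm_params(pi1, m1y, m2y, vy))
  m1a <- mean(a[lo]); m2a <- mean(a[!lo])
  va <- (sum((a[lo] - m1a)^2) + sum((a[!lo] - m2a)^2)) / length(y)
  va <- max(va, 1e-4 * stats::var(a), 1e-8)
  cya <- (sum((y[lo] - m1y) * (a[lo] - m1a)) +
          sum((y[!lo] - m2y) * (a[!lo] - m2a))) / length(y)
  if (jitter) {
    sa <- stats::sd(a)
    m1a <- m1a + stats::rnorm(1, sd = sa)
    m2a <- m2a + stats::rnorm(1, sd = sa)
    va <- va * exp(stats::runif(1, -0.7, 0.7))
    cya <- cya * stats::runif(1, 0, 1)
  }
  # keep the start positive definite
  lim <- 0.95 * sqrt(vy * va)
  cya <- max(min(cya, lim), -lim)
  gmm_params(pi1, m1y, m2y, vy, m1a, m2a, va, cya)
}

## One EM run from a given start.  Returns NULL when the degeneracy floor is
## hit; otherwise a list(params, loglik, trace, n_iter, converged).
em_run <- function(y, a, start, control) {
  n <- length(y)
  use_aux <- !is.null(a)
  p <- start
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ## E-step
    lc <- if (use_aux) logcomp_b(p, y, a) else logcomp_y(p, y)
    l1 <- log(p$pi1) + lc[, 1L]
    l2 <- log1p(-p$pi1) + lc[, 2L]
    m <- pmax(l1, l2)
    ll <- mean(m + log(exp(l1 - m) + exp(l2 - m)))
    trace <- c(trace, ll)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) < control$tol * (abs(ll_old) + control$tol)) {
      converged <- TRUE
      break
    }
    if (iter > control$max_iter) break
    ll_old <- ll
    g <- 1 / (1 + exp(l2 - l1))
    ## M-step
    s1 <- sum(g); s0 <- n - s1
    if (s1 < 1e-10 || s0 < 1e-10) return(NULL)  # empty component
    pi1 <- s1 / n
    pi1 <- min(max(pi1, 1e-12), 1 - 1e-12)
    m1y <- sum(g * y) / s1
    m2y <- sum((1 - g) * y) / s0
    d1y <- y - m1y; d2y <- y - m2y
    vy <- (sum(g * d1y^2) + sum((1 - g) * d2y^2)) / n
    if (!use_aux) {
      if (vy < control$variance_floor) return(NULL)
      p <- unflatten_params(c(pi1, m1y, m2y, vy), validate = FALSE)
    } else {
      m1a <- sum(g * a) / s1
      m2a <- sum((1 - g) * a) / s0
      d1a <- a - m1a; d2a <- a - m2a
      va <- (sum(g * d1a^2) + sum((1 - g) * d2a^2)) / n
      cya <- (sum(g * d1y * d1a) + sum((1 - g) * d2y * d2a)) / n
      ## eigenvalues of the 2x2 covariance
      tr <- vy + va
      dt <- vy * va - cya * cya
      disc <- max(tr * tr - 4 * dt, 0)
      lam_min <- (tr - sqrt(disc)) / 2
      if (lam_min < control$variance_floor) return(NULL)
      p <- unflatten_params(c(pi1, m1y, m2y, vy, m1a, m2a, va, cya),
                            validate = FALSE)
    }
  }
  ## spuriousness flags (see fit_control): the caller prefers clean
  ## solutions but can fall back when no restart yields one
  flag <- "ok"
  mc <- if (is.null(control$min_count)) 0 else control$min_count
  ms <- if (is.null(control$min_separation)) 0 else control$min_separation
  dm <- c(p$mu1y - p$mu2y, if (use_aux) p$mu1a - p$mu2a)
  sep2 <- if (use_aux) sum(dm * solve(cov_matrix(p), dm))
          else dm^2 / p$sigma_y2
  if (ms > 0 && sep2 < ms^2) flag <- "collapsed"
  else if (n * min(p$pi1, 1 - p$pi1) < mc) flag <- "small_count"
  list(params = p, loglik = trace[length(trace)], trace = trace,
       n_iter = iter, converged = converged, flag = flag)
}

#' Maximum likelihood fit of the two-component mixture by EM
#'
#' Maximizes the average observed-data log-likelihood: the joint
#' \eqn{\ell_b(\beta)} over \eqn{(y, a)} when \code{use_auxiliary} is
#' \code{TRUE}, the marginal \eqn{\ell_y(\theta)} over \eqn{y} otherwise.
#' Multiple restarts guard against local modes; the expectation step uses
#' posterior responsibilities, the maximization step is in closed form with
#' the covariance pooled across components.
#'
#' @param data An \code{"aux_dataset"}.
#' @param use_auxiliary Fit the joint (y, a) model (requires \code{data$a}).
#' @param control A \code{\link{fit_control}} list.
#' @return An object of class \code{"gmm_fit"}: list with \code{params}
#'   (\code{"gmm_params"}), \code{loglik_per_obs} (maximized average
#'   log-likelihood), \code{responsibilities} (n x 2 posterior matrix),
#'   \code{trace}, \code{n_iter}, \code{converged}, \code{n_restarts_used},
#'   \code{best_restart_logliks}, \code{use_auxiliary}, \code{n}.
#' @export
fit_gmm <- function(data, use_auxiliary = !is.null(data$a),
                    control = fit_control()) {
  stopifnot(inherits(data, "aux_dataset"))
  if (data$n < 5L) stop("need at least 5 observations to fit the mixture")
  if (use_auxiliary && is.null(data$a))
    stop("use_auxiliary = TRUE but the dataset has no auxiliary column")
  if (!is.null(control$seed)) set.seed(control$seed)
  y <- data$y
  a <- if (use_auxiliary) data$a else NULL
  best <- list(ok = NULL, small_count = NULL, collapsed = NULL)
  logliks <- rep(NA_real_, control$n_restarts)
  for (r in seq_len(control$n_restarts)) {
    ## restart 1: median split on y; restart 2 (joint fits): median split on
    ## a; remaining restarts: jittered y-split moments
    split_on <- if (r == 2L && use_auxiliary) "a" else "y"
    start <- em_start(y, a, split_on = split_on,
                      jitter = r > 2L || (r == 2L && !use_auxiliary))
    run <- em_run(y, a, start, control)
    if (is.null(run)) next  # degenerate restart discarded
    logliks[r] <- run$loglik
    if (is.null(best[[run$flag]]) || run$loglik > best[[run$flag]]$loglik)
      best[[run$flag]] <- run
  }
  ## prefer a clean solution; if every converged restart is spurious, fall
  ## back to the least pathological one (small-weight before collapse) so a
  ## long simulation does not die on one awkward sample
  pick <- best$ok
  if (is.null(pick)) {
    pick <- if (!is.null(best$small_count)) best$small_count else best$collapsed
    if (!is.null(pick))
      warning("no non-spurious EM solution found (", pick$flag,
              "); returning the best spurious fit", call. = FALSE)
  }
  if (is.null(pick))
    stop("all EM restarts hit the degeneracy floor; fit is degenerate")
  resp <- posterior_z(pick$params, y, a)
  structure(list(params = pick$params, loglik_per_obs = pick$loglik,
                 responsibilities = resp, trace = pick$trace,
                 n_iter = pick$n_iter, converged = pick$converged,
                 spurious = pick$flag != "ok",
                 n_restarts_used = control$n_restarts,
                 best_restart_logliks = logliks,
                 use_auxiliary = use_auxiliary, n = data$n),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("Two-component GMM fit",
      if (x$use_auxiliary) "(joint y, a)" else "(y-only)",
      sprintf("| n = %d | avg loglik = %.6f | iters = %d | converged: %s\n",
              x$n, x$loglik_per_obs, x$n_iter, x$converged))
  print(x$params)
  invisible(x)
}

#' Complete-data maximum likelihood fit (oracle)
#'
#' Closed-form MLE of the primary block \eqn{\theta} when the latent labels
#' are treated as observed: the mixing weight is the label mean, the
#' component means are per-label sample means of \eqn{y}, and the shared
#' variance is the pooled within-label variance with divisor \eqn{n}.
#'
#' @param data An \code{"aux_dataset"} with \code{z} present.
#' @param variance_floor Error when the pooled variance falls below this.
#' @return A \code{"gmm_fit"} (y-only, with degenerate one-step trace).
#' @export
fit_complete <- function(data, variance_floor = 1e-8) {
  stopifnot(inherits(data, "aux_dataset"))
  if (is.null(data$z)) stop("complete-data fit requires latent labels z")
  z <- data$z; y <- data$y; n <- data$n
  n1 <- sum(z == 1); n0 <- n - n1
  if (n1 == 0L || n0 == 0L) stop("a label class is empty; fit is degenerate")
  pi1 <- n1 / n
  m1 <- mean(y[z == 1]); m2 <- mean(y[z == 0])
  v <- (sum((y[z == 1] - m1)^2) + sum((y[z == 0] - m2)^2)) / n
  if (v < variance_floor)
    stop("pooled within-label variance below the floor; fit is degenerate")
  params <- gmm_params(pi1, m1, m2, v)
  ll <- mean(logdensity_x(params, y, z))
  structure(list(params = params, loglik_per_obs = ll,
                 responsibilities = cbind(z1 = z, z0 = 1 - z),
                 trace = ll, n_iter = 1L, converged = TRUE, spurious = FALSE,
                 n_restarts_used = 0L, best_restart_logliks = ll,
                 use_auxiliary = FALSE, n = n),
            class = "gmm_fit")
}
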