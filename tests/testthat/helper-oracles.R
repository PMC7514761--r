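# Independent oracle implementations used to check the package's densities
# and losses.  They deliberately avoid the package's code paths: matrix
# algebra goes through solve()/determinant(), mixtures are summed on the
# probability scale.

oracle_dbnorm <- function(b, mu, Sigma) {
  d <- b - mu
  q <- drop(t(d) %*% solve(Sigma) %*% d)
  exp(-0.5 * q) / (2 * pi * sqrt(det(Sigma)))
}

oracle_joint_density <- function(params, y, a) {
  S <- matrix(c(params$sigma_y2, params$sigma_ya,
                params$sigma_ya, params$sigma_a2), 2, 2)
  params$pi1 * oracle_dbnorm(c(y, a), c(params$mu1y, params$mu1a), S) +
    (1 - params$pi1) * oracle_dbnorm(c(y, a), c(params$mu2y, params$mu2a), S)
}

oracle_y_density <- function(params, y) {
  s <- sqrt(params$sigma_y2)
  params$pi1 * exp(-0.5 * ((y - params$mu1y) / s)^2) / (sqrt(2 * pi) * s) +
    (1 - params$pi1) * exp(-0.5 * ((y - params$mu2y) / s)^2) / (sqrt(2 * pi) * s)
}

# expected log N(y; mu, s2) under Y ~ N(m, v), closed form
oracle_e_lognormal <- function(m, v, mu, s2) {
  -0.5 * log(2 * pi * s2) - (v + (m - mu)^2) / (2 * s2)
}

# closed-form complete-data loss against the simulation truth (one label
# assignment; no quadrature)
oracle_loss_x <- function(params) {
  -(0.6 * (log(params$pi1) +
             oracle_e_lognormal(-1.2, 0.7, params$mu1y, params$sigma_y2)) +
    0.4 * (log(1 - params$pi1) +
             oracle_e_lognormal(1.2, 0.7, params$mu2y, params$sigma_y2)))
}

# true Case-1 parameters
theta0 <- function() gmm_params(0.6, -1.2, 1.2, 0.7)
beta0 <- function() gmm_params(0.6, -1.2, 1.2, 0.7, 1.8, -1.8, 0.49, 0)

# random valid parameter vectors for property-style loops
random_params <- function(aux = TRUE) {
  repeat {
    p <- try(if (aux) {
      sy <- runif(1, 0.2, 3); sa <- runif(1, 0.2, 3)
      gmm_params(runif(1, 0.05, 0.95), rnorm(1, 0, 2), rnorm(1, 0, 2), sy,
                 rnorm(1, 0, 2), rnorm(1, 0, 2), sa,
                 runif(1, -0.8, 0.8) * sqrt(sy * sa))
    } else {
      gmm_params(runif(1, 0.05, 0.95), rnorm(1, 0, 2), rnorm(1, 0, 2),
                 runif(1, 0.2, 3))
    }, silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

# average Y-marginal log-likelihood of a fit (the criteria's goodness input)
elly_of_fit <- function(fit, data) mean(logdensity_y(fit$params, data$y))

# align an estimated theta to the truth's labelling (component 1 = lower mean)
align_to_truth <- function(params) {
  if (params$mu1y <= params$mu2y) params else swap_components(params)
}
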