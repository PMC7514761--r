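#' Gauss-Hermite nodes and weights
#'
#' Computes the nodes and weights of the n-point Gauss-Hermite rule for
#' integrals of the form \eqn{\int e^{-x^2} f(x) dx}, via the Golub-Welsch
#' eigendecomposition of the Jacobi matrix.
#'
#' @param n Number of nodes.
#' @return A list with numeric vectors \code{nodes} and \code{weights}.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1L)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(1:(n - 1L), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = sqrt(pi) * (e$vectors[1L, idx])^2)
}

## E_{Y ~ N(m, v)}[ f(Y) ] by Gauss-Hermite
gh_expect <- function(f, m, v, rule) {
  y <- m + sqrt(2 * v) * rule$nodes
  sum(rule$weights * f(y)) / sqrt(pi)
}
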