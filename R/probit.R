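#' Probit link function
#'
#' \code{probit_link(x, sigma)} returns \eqn{\Phi(x/\sigma)}, the
#' probability of observing a \code{+1} at an entry whose latent value is
#' \code{x} when the additive noise is mean-zero Gaussian with standard
#' deviation \code{sigma}. Equivalently, the probability that
#' \eqn{x + z \ge 0} for \eqn{z \sim N(0, \sigma^2)}.
#'
#' @param x numeric vector or matrix of latent values.
#' @param sigma positive noise standard deviation.
#' @return probabilities in \[0, 1\], same shape as \code{x}.
#' @export
probit_link <- function(x, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive scalar", call. = FALSE)
  stats::pnorm(x / sigma)
}

#' Probit log-likelihood over the observed entries
#'
#' The log-likelihood of a latent matrix \code{X} given the observed
#' \code{+1}/\code{-1} labels:
#' \deqn{F(X) = \sum_{(i,j) \in \Omega} \log \Phi(a_{ij} x_{ij} / \sigma),}
#' using \eqn{1 - \Phi(t) = \Phi(-t)}. Unobserved entries do not
#' contribute. Always \eqn{\le 0}; approaches 0 only when every observed
#' label is predicted with probability near 1. Computed through the
#' log-scale normal CDF so that strongly negative margins
#' (\eqn{x/\sigma < -8}) do not underflow to \code{-Inf}.
#'
#' @param X real latent matrix, conformable with \code{A}.
#' @param A an [obs_matrix]; must have at least one observed entry.
#' @param sigma positive noise standard deviation.
#' @return the scalar log-likelihood.
#' @export
probit_loglik <- function(X, A, sigma) {
  check_conformable(X, A)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  a <- unclass(A)
  obs <- !is.na(a)
  if (!any(obs)) stop("nothing to fit: no observed entries", call. = FALSE)
  sum(stats::pnorm(a[obs] * X[obs] / sigma, log.p = TRUE))
}

#' Gradient of the probit log-likelihood
#'
#' Elementwise derivative of [probit_loglik] with respect to \code{X}:
#' \deqn{\partial F/\partial x_{ij} =
#'   a_{ij}\,\phi(x_{ij}/\sigma) / (\sigma\,\Phi(a_{ij} x_{ij}/\sigma))}
#' at observed positions and exactly 0 elsewhere. The ratio
#' \eqn{\phi/\Phi} (inverse Mills ratio) is evaluated as
#' \code{exp(log phi - log Phi)} for numerical stability at large negative
#' margins.
#'
#' @inheritParams probit_loglik
#' @return a matrix of the same shape as \code{X}.
#' @export
probit_grad <- function(X, A, sigma) {
  check_conformable(X, A)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  a <- unclass(A)
  obs <- !is.na(a)
  if (!any(obs)) stop("nothing to fit: no observed entries", call. = FALSE)
  G <- matrix(0, nrow(X), ncol(X))
  z <- X[obs] / sigma
  az <- a[obs] * z
  G[obs] <- a[obs] *
    exp(stats::dnorm(z, log = TRUE) - stats::pnorm(az, log.p = TRUE)) / sigma
  G
}
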