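#' Soft-threshold level for the nuclear-norm ball
#'
#' Given singular values sorted nonincreasing and a radius \code{tau},
#' returns the smallest \eqn{\lambda \ge 0} such that
#' \eqn{\sum_i \max(\sigma_i - \lambda, 0) \le \tau}. This is the exact
#' water-filling solution computed in closed form per sorted prefix: for
#' the active prefix of length k, \eqn{\lambda_k = (\sum_{i \le k}
#' \sigma_i - \tau)/k}, and the valid k is the one with
#' \eqn{\sigma_{k+1} \le \lambda_k < \sigma_k}. Returns 0 when the values
#' already sum to at most \code{tau}.
#'
#' @param d numeric vector of singular values, nonincreasing, all >= 0.
#' @param tau positive radius of the nuclear-norm ball.
#' @return the scalar threshold \eqn{\lambda}.
#' @export
soft_threshold_level <- function(d, tau) {
  if (any(d < 0)) stop("negative singular value", call. = FALSE)
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
  if (is.unsorted(rev(d))) stop("'d' must be sorted nonincreasing",
                                call. = FALSE)
  if (sum(d) <= tau) return(0)
  cs <- cumsum(d)
  k <- seq_along(d)
  lam_k <- (cs - tau) / k
  # valid prefix: lambda_k < d_k (those values stay active) and
  # lambda_k >= d_{k+1} (the rest are zeroed); the largest such k is exact
  d_next <- c(d[-1L], 0)
  ok <- lam_k < d & lam_k >= d_next
  lam_k[which(ok)[1L]]
}

#' Euclidean projection onto the nuclear-norm ball
#'
#' Projects a real matrix onto \eqn{\{Y : \|Y\|_* \le \tau\}} by
#' singular-value soft-thresholding: with \eqn{X = U \Sigma V^T},
#' \eqn{P(X) = U \max(\Sigma - \lambda I, 0) V^T} where \eqn{\lambda} is
#' the exact level from [soft_threshold_level]. The projection is the
#' identity when \eqn{\|X\|_* \le \tau}, idempotent, and non-expansive.
#'
#' @param X real matrix with finite entries.
#' @param tau positive radius.
#' @return the projected matrix.
#' @details Singular values below \code{1e-12} are treated as exact zeros
#'   before thresholding (numerical rank noise). A full dense SVD is used;
#'   the problem sizes this package targets (hundreds by tens) make a
#'   truncated SVD unnecessary, and the exact threshold needs the whole
#'   spectrum anyway.
#' @export
project_nuclear_ball <- function(X, tau) {
  if (!all(is.finite(X))) stop("non-finite entries in 'X'", call. = FALSE)
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
  sv <- svd(X)
  d <- sv$d
  d[d < 1e-12] <- 0
  if (sum(d) <= tau) return(X)
  lam <- soft_threshold_level(d, tau)
  dthr <- pmax(d - lam, 0)
  keep <- dthr > 0
  if (!any(keep)) return(matrix(0, nrow(X), ncol(X)))
  sv$u[, keep, drop = FALSE] %*%
    (dthr[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Nuclear norm
#'
#' Sum of the singular values of a matrix.
#' @param X a real matrix.
#' @return nonnegative scalar.
#' @export
nuclear_norm <- function(X) sum(svd(X, nu = 0, nv = 0)$d)
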