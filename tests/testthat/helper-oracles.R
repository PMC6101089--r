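# Independent oracles used to freeze or cross-check expected values.
# These deliberately use different algorithms from the package internals.

# standard normal CDF via the error-function Taylor/continued series,
# independent of stats::pnorm
phi_cdf_series <- function(x) {
  erf <- function(z) {
    # Taylor series, adequate for |z| <= 4 at double precision
    k <- 0:60
    s <- sum((-1)^k * z^(2 * k + 1) / (factorial(k) * (2 * k + 1)))
    2 / sqrt(pi) * s
  }
  0.5 * (1 + erf(x / sqrt(2)))
}

# AUC by exhaustive pair counting (Mann-Whitney definition)
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels != 1]
  tot <- 0
  for (sp in pos) tot <- tot + sum(sp > neg) + 0.5 * sum(sp == neg)
  tot / (length(pos) * length(neg))
}

# AUPR by an exhaustive sweep over every distinct threshold
aupr_sweep_oracle <- function(scores, labels) {
  y <- labels == 1
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y)
  ap <- 0
  r_prev <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(y[sel]) / sum(sel)
    rec <- sum(y[sel]) / n1
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

# smallest lambda with sum(max(d - lambda, 0)) <= tau, by bisection
lambda_bisect_oracle <- function(d, tau, tol = 1e-14) {
  if (sum(d) <= tau) return(0)
  lo <- 0; hi <- max(d)
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (sum(pmax(d - mid, 0)) <= tau) hi <- mid else lo <- mid
  }
  hi
}

# Euclidean projection of nonnegative values onto {y >= 0, sum(y) <= tau}
# (Duchi et al. sort/cumsum algorithm), recombined with the SVD factors:
# an independent route to the nuclear-ball projection
project_nuclear_oracle <- function(X, tau) {
  sv <- svd(X)
  d <- sv$d
  if (sum(d) <= tau) return(X)
  u <- sort(d, decreasing = TRUE)
  cs <- cumsum(u)
  j <- seq_along(u)
  rho <- max(j[u - (cs - tau) / j > 0])
  theta <- (cs[rho] - tau) / rho
  dthr <- pmax(d - theta, 0)
  sv$u %*% (dthr * t(sv$v))
}

# central finite differences of the probit log-likelihood
fd_gradient_oracle <- function(X, A, sigma, h = 1e-5) {
  G <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    Xp <- X; Xp[i, j] <- X[i, j] + h
    Xm <- X; Xm[i, j] <- X[i, j] - h
    G[i, j] <- (probit_loglik(Xp, A, sigma) -
                  probit_loglik(Xm, A, sigma)) / (2 * h)
  }
  G
}

# one-dimensional probit MLE by Newton iteration for a single +/-1 label
probit_mle_1d_oracle <- function(a, sigma, x0 = 0, iters = 50) {
  x <- x0
  for (k in seq_len(iters)) {
    z <- x / sigma
    g <- a * exp(dnorm(z, log = TRUE) - pnorm(a * z, log.p = TRUE)) / sigma
    # Hessian of log Phi(a x / sigma)
    mills <- exp(dnorm(z, log = TRUE) - pnorm(a * z, log.p = TRUE))
    hess <- -(mills * (a * z + mills)) / sigma^2
    x <- x - g / hess
  }
  x
}

# deterministic random obs_matrix fixtures
random_obs_matrix <- function(p, q, frac_obs = 0.8, seed = 1) {
  set.seed(seed)
  v <- matrix(sample(c(1, -1), p * q, replace = TRUE), p, q)
  v[runif(p * q) > frac_obs] <- NA
  if (all(is.na(v))) v[1, 1] <- 1
  dimnames(v) <- list(paste0("m", 1:p), paste0("d", 1:q))
  obs_matrix(v)
}
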