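#' Generate a low-rank latent matrix
#'
#' Draws \code{X = L R'} with \code{L} (p x rank) and \code{R} (q x rank)
#' filled with independent mean-zero Gaussians, scaled so the marginal
#' standard deviation of each entry of \code{X} equals
#' \code{latent_scale}. The rank equals \code{true_rank} almost surely.
#'
#' @param p,q matrix dimensions.
#' @param true_rank rank of the latent matrix, at most \code{min(p, q)}.
#' @param latent_scale entrywise standard deviation of the latent matrix.
#' @param seed integer seed; draws are bitwise reproducible.
#' @return a \code{p x q} numeric matrix.
#' @export
generate_latent <- function(p, q, true_rank, latent_scale = 1, seed = 0L) {
  if (true_rank > min(p, q))
    stop("'true_rank' cannot exceed min(p, q)", call. = FALSE)
  if (latent_scale <= 0) stop("'latent_scale' must be positive",
                              call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # entry variance of LR' is rank * var_L * var_R
  sdf <- sqrt(latent_scale / sqrt(true_rank))
  L <- matrix(stats::rnorm(p * true_rank, sd = sdf), p, true_rank)
  R <- matrix(stats::rnorm(q * true_rank, sd = sdf), q, true_rank)
  X <- L %*% t(R)
  dimnames(X) <- list(paste0("m", seq_len(p)), paste0("d", seq_len(q)))
  X
}

#' Sample binary observations from a latent matrix
#'
#' Applies the generative observation model: each entry receives additive
#' Gaussian noise \eqn{z_{ij} \sim N(0, \sigma^2)} and is labelled
#' \code{+1} when \eqn{x_{ij} + z_{ij} \ge 0}, else \code{-1} — so
#' \eqn{P(a_{ij} = +1) = \Phi(x_{ij}/\sigma)}. Each position enters the
#' observed set independently with probability \code{obs_frac}, i.e. the
#' number of observed entries is Binomial(pq, obs_frac) rather than fixed.
#'
#' @param X_true real latent matrix.
#' @param noise_sigma positive noise standard deviation.
#' @param obs_frac probability that a given entry is observed.
#' @param seed integer seed.
#' @return an [obs_matrix] with unobserved entries \code{NA}.
#' @export
sample_observations <- function(X_true, noise_sigma, obs_frac, seed = 0L) {
  if (noise_sigma < 0) stop("'noise_sigma' must be nonnegative",
                            call. = FALSE)
  if (obs_frac <= 0 || obs_frac > 1)
    stop("'obs_frac' must be in (0, 1]", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  p <- nrow(X_true); q <- ncol(X_true)
  Z <- if (noise_sigma > 0)
    matrix(stats::rnorm(p * q, sd = noise_sigma), p, q)
  else matrix(0, p, q)
  lab <- ifelse(X_true + Z >= 0, 1, -1)
  mask <- matrix(stats::runif(p * q) < obs_frac, p, q)
  lab[!mask] <- NA
  if (is.null(dimnames(X_true)))
    dimnames(lab) <- list(paste0("m", seq_len(p)), paste0("d", seq_len(q)))
  else dimnames(lab) <- dimnames(X_true)
  obs_matrix(lab)
}

#' Build a train/test benchmark from the generative model
#'
#' Generates a latent matrix, samples binary observations from it, and
#' splits the observed entries into a disjoint training matrix and a
#' held-out labelled test set drawn from the same latent matrix.
#'
#' @param p,q,true_rank,latent_scale,seed passed to [generate_latent].
#' @param noise_sigma,obs_frac passed to [sample_observations].
#' @param test_frac fraction of observed entries held out for testing.
#' @return a list with \code{train} (an [obs_matrix]), \code{test} (a data
#'   frame with columns \code{i}, \code{j}, \code{label}), \code{X_true},
#'   and the generating configuration \code{config}.
#' @export
make_benchmark <- function(p, q, true_rank, latent_scale = 1,
                           noise_sigma = 0.2, obs_frac = 0.8,
                           test_frac = 0.2, seed = 0L) {
  if (test_frac < 0 || test_frac >= 1)
    stop("'test_frac' must be in [0, 1)", call. = FALSE)
  X_true <- generate_latent(p, q, true_rank, latent_scale, seed = seed)
  A <- sample_observations(X_true, noise_sigma, obs_frac, seed = seed + 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) + 2L)
  ij <- observed_index(A)
  n_test <- floor(test_frac * nrow(ij))
  test_rows <- sort(sample.int(nrow(ij), n_test))
  v <- unclass(A)
  test <- data.frame(i = ij[test_rows, 1L], j = ij[test_rows, 2L],
                     label = v[ij[test_rows, , drop = FALSE]])
  v[ij[test_rows, , drop = FALSE]] <- NA
  list(train = obs_matrix(v), test = test, X_true = X_true,
       config = list(p = p, q = q, true_rank = true_rank,
                     latent_scale = latent_scale,
                     noise_sigma = noise_sigma, obs_frac = obs_frac,
                     test_frac = test_frac, seed = seed))
}
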