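#' Fit a one-bit matrix completion model
#'
#' Recovers a low-rank real-valued latent matrix \eqn{X} from the observed
#' \code{+1}/\code{-1} entries of a bipartite adjacency matrix by
#' maximizing the probit log-likelihood
#' \deqn{\sum_{(i,j)\in\Omega} \log \Phi(a_{ij} x_{ij}/\sigma)
#'   \quad \mathrm{s.t.} \quad \|X\|_* \le \sqrt{r p q},}
#' where \eqn{\sigma} is the assumed noise standard deviation and \eqn{r}
#' the expected rank. The nuclear-norm ball stands in for the rank
#' constraint; the optimization is a nonmonotone spectral projected
#' gradient descent on the negative log-likelihood, with singular-value
#' soft-thresholding as the projection. Entries of the fitted latent
#' matrix are the prediction scores: larger \eqn{\hat x_{ij}} means the
#' pair is more likely a true association.
#'
#' @param A an [obs_matrix] (or a plain \code{+1}/\code{-1}/\code{NA}
#'   matrix, coerced) with at least one observed entry.
#' @param sigma positive noise standard deviation of the probit link.
#' @param r expected rank, an integer in \code{1..min(p, q)}. Exactly one
#'   of \code{r} and \code{r_ratio} must be given.
#' @param r_ratio alternative rank specification as a fraction of
#'   \code{r_max = min(p, q)}; mapped to \code{r = max(1,
#'   round(r_ratio * r_max))}.
#' @param control an [spg_control] list of solver settings.
#' @return an object of class \code{"onebitmc"}: a list with the fitted
#'   latent matrix \code{X}, the data \code{A}, the model parameters
#'   \code{sigma}, \code{r}, \code{tau}, the final \code{logLik}, the
#'   solver report (\code{objective_trace} of the negative log-likelihood,
#'   \code{n_iter}, \code{converged}, \code{residual}) and the matched
#'   \code{call}.
#' @details Initialization is the zero matrix (feasible for any radius and
#'   symmetric between the classes); the fit is fully deterministic. The
#'   latent scale is identifiable only jointly with \code{sigma} (scaling
#'   both leaves the likelihood unchanged), so scores should be compared
#'   within a fit, not across fits with different \code{sigma}.
#' @examples
#' set.seed(1)
#' sim <- make_benchmark(p = 20, q = 10, true_rank = 2, noise_sigma = 0.2,
#'                       obs_frac = 0.8, seed = 1)
#' fit <- onebitmc(sim$train, sigma = 0.2, r = 2)
#' fit
#' head(coef(fit))
#' @export
onebitmc <- function(A, sigma = 0.2, r = NULL, r_ratio = NULL,
                     control = spg_control()) {
  if (!inherits(A, "obs_matrix")) A <- obs_matrix(as.matrix(A))
  p <- nrow(A); q <- ncol(A)
  r_max <- min(p, q)
  if (is.null(r) == is.null(r_ratio))
    stop("give exactly one of 'r' and 'r_ratio'", call. = FALSE)
  if (!is.null(r_ratio)) r <- max(1L, as.integer(round(r_ratio * r_max)))
  r <- as.integer(r)
  if (r < 1L || r > r_max)
    stop("'r' must be in 1..min(p, q) = 1..", r_max, call. = FALSE)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (n_observed(A) == 0L)
    stop("nothing to fit: no observed entries", call. = FALSE)
  tau <- sqrt(r * p * q)

  rep_ <- spg_minimize(
    fn = function(X) -probit_loglik(X, A, sigma),
    gr = function(X) -probit_grad(X, A, sigma),
    project = function(X) project_nuclear_ball(X, tau),
    X0 = matrix(0, p, q),
    control = control)

  X <- rep_$X_hat
  dimnames(X) <- dimnames(A)
  structure(list(X = X, A = A, sigma = sigma, r = r, tau = tau,
                 logLik = -rep_$objective_trace[length(rep_$objective_trace)],
                 objective_trace = rep_$objective_trace,
                 n_iter = rep_$n_iter, converged = rep_$converged,
                 residual = rep_$residual, control = control,
                 call = match.call()),
            class = "onebitmc")
}

#' @export
print.onebitmc <- function(x, ...) {
  cat("One-bit matrix completion fit (probit link)\n")
  cat(sprintf("  %d x %d matrix, %d observed entries\n",
              nrow(x$A), ncol(x$A), n_observed(x$A)))
  cat(sprintf("  sigma = %g, r = %d (nuclear-norm radius tau = %.4g)\n",
              x$sigma, x$r, x$tau))
  cat(sprintf("  log-likelihood %.4f after %d iterations (%s, residual %.3g)\n",
              x$logLik, x$n_iter,
              if (x$converged) "converged" else "iteration limit",
              x$residual))
  invisible(x)
}

#' @export
summary.onebitmc <- function(object, ...) {
  P <- probit_link(object$X, object$sigma)
  a <- unclass(object$A)
  obs <- !is.na(a)
  structure(list(fit = object,
                 effective_rank = sum(svd(object$X, nu = 0, nv = 0)$d > 1e-8),
                 nuclear_norm = nuclear_norm(object$X),
                 train_accuracy = mean(sign(object$X[obs]) == a[obs]),
                 mean_p_pos = mean(P[obs][a[obs] == 1]),
                 mean_p_neg = mean(P[obs][a[obs] == -1])),
            class = "summary.onebitmc")
}

#' @export
print.summary.onebitmc <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  effective rank %d, nuclear norm %.4g (radius %.4g)\n",
              x$effective_rank, x$nuclear_norm, x$fit$tau))
  cat(sprintf("  training sign accuracy %.3f\n", x$train_accuracy))
  cat(sprintf("  mean fitted P(+1): %.3f at observed positives, %.3f at observed negatives\n",
              x$mean_p_pos, x$mean_p_neg))
  invisible(x)
}

#' @export
coef.onebitmc <- function(object, ...) object$X

#' @export
logLik.onebitmc <- function(object, ...) {
  structure(object$logLik, df = NA_integer_, nobs = n_observed(object$A),
            class = "logLik")
}

#' @export
fitted.onebitmc <- function(object, ...) probit_link(object$X, object$sigma)

#' Predictions from a one-bit matrix completion fit
#'
#' @param object a fitted [onebitmc] model.
#' @param pairs optional two-column matrix or data frame of (row, column)
#'   indices, or of row/column identifiers; default all cells.
#' @param type \code{"link"} for latent scores \eqn{\hat x_{ij}} (the
#'   ranking scale), \code{"response"} for probabilities
#'   \eqn{\Phi(\hat x_{ij}/\sigma)}.
#' @param ... unused.
#' @return a matrix when \code{pairs} is \code{NULL}, else a vector.
#' @export
predict.onebitmc <- function(object, pairs = NULL,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  M <- if (type == "link") object$X else fitted(object)
  if (is.null(pairs)) return(M)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("'pairs' needs two columns", call. = FALSE)
  if (!is.numeric(pairs)) {
    i <- match(pairs[, 1L], rownames(object$A))
    j <- match(pairs[, 2L], colnames(object$A))
    if (anyNA(i) || anyNA(j))
      stop("unknown row or column identifier in 'pairs'", call. = FALSE)
    pairs <- cbind(i, j)
  }
  M[pairs]
}

#' @export
residuals.onebitmc <- function(object, ...) {
  a <- unclass(object$A)
  r <- (a + 1) / 2 - fitted(object)
  r[is.na(a)] <- NA
  r
}

#' Simulate new observations from a fitted model
#'
#' Draws new \code{+1}/\code{-1} labels at the observed positions from the
#' fitted probabilities \eqn{\Phi(\hat x_{ij}/\sigma)} (a parametric
#' bootstrap of the observation model).
#'
#' @param object a fitted [onebitmc] model.
#' @param nsim number of replicate matrices.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of \code{nsim} [obs_matrix] objects with the same Omega
#'   as the training data.
#' @export
simulate.onebitmc <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- fitted(object)
  a <- unclass(object$A)
  obs <- !is.na(a)
  lapply(seq_len(nsim), function(k) {
    v <- a
    v[obs] <- ifelse(stats::runif(sum(obs)) < P[obs], 1, -1)
    obs_matrix(v)
  })
}

#' @param x a fitted [onebitmc] model.
#' @param ... passed to [plot].
#' @describeIn onebitmc plots the negative log-likelihood trace over SPG
#'   iterations.
#' @export
plot.onebitmc <- function(x, ...) {
  plot(seq_along(x$objective_trace) - 1L, x$objective_trace,
       type = "l", xlab = "iteration",
       ylab = "negative log-likelihood", ...)
  invisible(x)
}
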