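#' Control parameters for the spectral projected gradient solver
#'
#' Defaults follow the standard SPG2 recommendations: Barzilai-Borwein
#' spectral steps clamped to \code{[alpha_min, alpha_max]}, a nonmonotone
#' Armijo line search over the last \code{memory} objective values with
#' sufficient-decrease parameter \code{gamma}, and a stopping rule on the
#' Frobenius norm of the projected-gradient residual
#' \eqn{\|P_C(X - g(X)) - X\|_F \le tol}.
#'
#' @param max_iter maximum number of iterations (default 300).
#' @param tol stopping threshold on the projected-gradient residual
#'   (default 1e-6).
#' @param memory nonmonotone line-search history length (default 10).
#' @param gamma sufficient-decrease parameter in (0, 1) (default 1e-4).
#' @param alpha_min,alpha_max bounds on the spectral step
#'   (defaults 1e-10, 1e10).
#' @param alpha0 initial step; \code{NULL} (default) uses
#'   \eqn{1/\|g(X_0)\|_\infty}, clamped to the bounds.
#' @return a list of class \code{"spg_control"}.
#' @export
spg_control <- function(max_iter = 300L, tol = 1e-6, memory = 10L,
                        gamma = 1e-4, alpha_min = 1e-10, alpha_max = 1e10,
                        alpha0 = NULL) {
  stopifnot(max_iter >= 0, tol > 0 || is.infinite(tol), memory >= 1,
            gamma > 0, gamma < 1, alpha_min > 0, alpha_min < alpha_max)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 memory = as.integer(memory), gamma = gamma,
                 alpha_min = alpha_min, alpha_max = alpha_max,
                 alpha0 = alpha0),
            class = "spg_control")
}

#' Nonmonotone spectral projected gradient minimization
#'
#' Minimizes a smooth function over a closed convex set given by a
#' projection operator, using the SPG2 variant: at each iteration the
#' feasible direction \eqn{d = P_C(X - \alpha g) - X} is searched by
#' nonmonotone backtracking (Armijo against the maximum of the last
#' \code{memory} objective values), and the spectral step is the
#' Barzilai-Borwein ratio \eqn{\langle s,s\rangle / \langle s,y\rangle},
#' clamped to the step bounds (set to \code{alpha_max} on nonpositive
#' curvature). Every iterate is feasible by construction.
#'
#' @param fn objective function of a matrix, smooth on the feasible set.
#' @param gr gradient function, returning a matrix of the same shape.
#' @param project projection onto the feasible set.
#' @param X0 feasible starting matrix (projected internally as a guard).
#' @param control an [spg_control] list.
#' @return a list with components \code{X_hat} (the final iterate),
#'   \code{objective_trace} (objective at \code{X0} and after each
#'   iteration, length \code{n_iter + 1}), \code{n_iter},
#'   \code{converged}, and \code{residual} (final projected-gradient
#'   Frobenius norm).
#' @export
spg_minimize <- function(fn, gr, project, X0, control = spg_control()) {
  X <- project(X0)
  f <- fn(X)
  if (!is.finite(f)) stop("objective not finite at the starting point",
                          call. = FALSE)
  g <- gr(X)
  trace <- f
  fhist <- rep(-Inf, control$memory)
  fhist[1L] <- f
  resid <- frob(project(X - g) - X)
  if (resid <= control$tol || control$max_iter == 0L)
    return(list(X_hat = X, objective_trace = trace, n_iter = 0L,
                converged = resid <= control$tol, residual = resid))

  alpha <- if (is.null(control$alpha0)) {
    gmax <- max(abs(g))
    if (gmax > 0) 1 / gmax else 1
  } else control$alpha0
  alpha <- min(max(alpha, control$alpha_min), control$alpha_max)

  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(control$max_iter)) {
    D <- project(X - alpha * g) - X
    gd <- sum(g * D)
    fmax <- max(fhist)
    lam <- 1
    repeat {
      Xn <- X + lam * D
      fn_new <- fn(Xn)
      if (fn_new <= fmax + control$gamma * lam * gd || lam < 1e-10) break
      # quadratic interpolation backtracking, safeguarded
      lam_q <- -0.5 * lam^2 * gd / (fn_new - f - lam * gd)
      lam <- if (is.finite(lam_q) && lam_q > 0.1 * lam && lam_q < 0.9 * lam)
        lam_q else lam / 2
    }
    gn <- gr(Xn)
    S <- Xn - X
    Y <- gn - g
    sy <- sum(S * Y)
    alpha <- if (sy <= 0) control$alpha_max else
      min(max(sum(S * S) / sy, control$alpha_min), control$alpha_max)
    X <- Xn; f <- fn_new; g <- gn
    n_iter <- it
    trace <- c(trace, f)
    fhist[(it %% control$memory) + 1L] <- f
    resid <- frob(project(X - g) - X)
    if (resid <= control$tol) { converged <- TRUE; break }
  }
  list(X_hat = X, objective_trace = trace, n_iter = n_iter,
       converged = converged, residual = resid)
}

# Frobenius norm
frob <- function(M) sqrt(sum(M * M))
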