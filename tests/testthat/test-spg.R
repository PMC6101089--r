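test_that("SPG solves projected least-squares to the closed-form solution", {
  set.seed(31)
  B <- matrix(rnorm(35, sd = 2), 7, 5)
  tau <- 0.4 * nuclear_norm(B)
  sol <- project_nuclear_ball(B, tau)

  accepted <- list() # gradient is evaluated once per accepted iterate
  rep_ <- spg_minimize(
    fn = function(X) 0.5 * sum((X - B)^2),
    gr = function(X) { accepted[[length(accepted) + 1L]] <<- X; X - B },
    project = function(X) project_nuclear_ball(X, tau),
    X0 = matrix(0, 7, 5),
    control = spg_control(tol = 1e-8))

  expect_true(rep_$converged)
  expect_lt(norm(rep_$X_hat - sol, "F"), 1e-6)
  expect_length(rep_$objective_trace, rep_$n_iter + 1L)
  expect_gte(rep_$residual, 0)

  # every accepted iterate feasible
  for (X in accepted)
    expect_lte(nuclear_norm(X), tau * (1 + 1e-6))
  # nonmonotone acceptance: each value no worse than the running
  # 10-iterate maximum (the Armijo slack term is nonpositive)
  tr <- rep_$objective_trace
  for (k in 2:length(tr))
    expect_lte(tr[k], max(tr[max(1, k - 10):(k - 1)]) + 1e-10)
  # best-so-far objective never worsens
  expect_true(all(diff(cummin(tr)) <= 0))
})

test_that("SPG matches an entrywise Newton oracle on a separable probit objective", {
  # two-sided per-entry objective: w1 log Phi(x/s) + w0 log Phi(-x/s),
  # whose entrywise maximizer is finite and independent across entries;
  # a huge radius makes the constraint inactive
  set.seed(32)
  p <- 4; q <- 3; s <- 0.5
  w1 <- matrix(sample(1:5, p * q, TRUE), p, q)
  w0 <- matrix(sample(1:5, p * q, TRUE), p, q)
  fn <- function(X) -sum(w1 * pnorm(X / s, log.p = TRUE) +
                           w0 * pnorm(-X / s, log.p = TRUE))
  gr <- function(X) {
    z <- X / s
    -(w1 * exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE)) -
        w0 * exp(dnorm(z, log = TRUE) - pnorm(-z, log.p = TRUE))) / s
  }
  rep_ <- spg_minimize(fn, gr, project = function(X)
    project_nuclear_ball(X, 1e6), X0 = matrix(0, p, q),
    control = spg_control(tol = 1e-10, max_iter = 2000))

  # independent oracle: 1-D Newton on each entry's weighted objective
  newton <- function(a1, a0) {
    x <- 0
    for (it in 1:100) {
      z <- x / s
      g <- (a1 * exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE)) -
              a0 * exp(dnorm(z, log = TRUE) - pnorm(-z, log.p = TRUE))) / s
      h <- 1e-6
      g2 <- (a1 * exp(dnorm((x + h) / s, log = TRUE) - pnorm((x + h) / s, log.p = TRUE)) -
               a0 * exp(dnorm((x + h) / s, log = TRUE) - pnorm(-(x + h) / s, log.p = TRUE))) / s
      x <- x - g * h / (g2 - g)
      if (abs(g) < 1e-14) break
    }
    x
  }
  Xstar <- matrix(mapply(newton, w1, w0), p, q)
  expect_lt(max(abs(rep_$X_hat - Xstar)), 1e-4)
})

test_that("an infinite tolerance returns the start point untouched", {
  B <- matrix(1:6 / 2, 2, 3)
  rep_ <- spg_minimize(function(X) sum(X^2), function(X) 2 * X,
                       function(X) X, B,
                       control = spg_control(tol = Inf))
  expect_identical(rep_$X_hat, B)
  expect_equal(rep_$n_iter, 0L)
  expect_length(rep_$objective_trace, 1L)
})

test_that("tightening the tolerance never worsens the reached objective", {
  set.seed(33)
  B <- matrix(rnorm(20), 5, 4)
  tau <- 0.5 * nuclear_norm(B)
  obj <- function(tol) {
    r <- spg_minimize(function(X) 0.5 * sum((X - B)^2),
                      function(X) X - B,
                      function(X) project_nuclear_ball(X, tau),
                      matrix(0, 5, 4), control = spg_control(tol = tol))
    min(r$objective_trace)
  }
  vals <- vapply(c(1e-2, 1e-4, 1e-6, 1e-8), obj, 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("a non-finite objective at the start is rejected", {
  expect_error(
    spg_minimize(function(X) NaN, function(X) X, function(X) X,
                 matrix(0, 2, 2)),
    "not finite")
})

test_that("model fitting is deterministic and respects the likelihood geometry", {
  # all-positive fully observed matrix with a generous radius: every
  # fitted entry must be pushed strictly positive
  Aall <- obs_matrix(matrix(1, 4, 3,
                            dimnames = list(paste0("m", 1:4),
                                            paste0("d", 1:3))))
  f <- onebitmc(Aall, sigma = 0.5, r = 3)
  expect_true(all(f$X > 0))
  expect_lte(nuclear_norm(f$X), f$tau * (1 + 1e-6))

  # bitwise-equal traces on identical reruns
  sim <- make_benchmark(25, 12, 2, noise_sigma = 0.2, obs_frac = 0.7,
                        seed = 5)
  f1 <- onebitmc(sim$train, sigma = 0.2, r = 2)
  f2 <- onebitmc(sim$train, sigma = 0.2, r = 2)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_identical(f1$X, f2$X)

  # recovery beats the uninformative zero matrix on held-out signs
  s <- predict(f1, pairs = sim$test[, 1:2])
  acc <- mean(sign(s) == sim$test$label)
  expect_gt(acc, 0.5)
})

test_that("fit argument validation catches misuse", {
  A <- random_obs_matrix(6, 4, seed = 1)
  expect_error(onebitmc(A, sigma = 0.2), "exactly one of")
  expect_error(onebitmc(A, sigma = 0.2, r = 2, r_ratio = 0.5),
               "exactly one of")
  expect_error(onebitmc(A, sigma = 0.2, r = 5), "1..min")
  expect_error(onebitmc(A, sigma = -1, r = 2), "positive")
  expect_equal(onebitmc(A, sigma = 0.2, r_ratio = 1 / 3,
                        control = spg_control(max_iter = 1))$r, 1L)
  expect_equal(onebitmc(A, sigma = 0.2, r_ratio = 1,
                        control = spg_control(max_iter = 1))$r, 4L)
})
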