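test_that("AUC handles perfect, inverted and tied rankings", {
  expect_equal(auc_score(c(3, 2, 1, 0), c(1, 1, -1, -1)), 1.0)
  expect_equal(auc_score(c(0, 1, 2, 3), c(1, 1, -1, -1)), 0.0)
  # pair counting: one clean win plus one tie out of two pairs
  expect_equal(auc_score(c(2, 2, 1), c(1, -1, -1)), 0.75)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUPR handles perfect and worst-case rankings", {
  expect_equal(aupr_score(c(4, 3, 2, 1), c(1, 1, -1, -1)), 1.0)
  # single positive ranked last among n: one PR point at (1, 1/n)
  for (n in c(4, 7, 10)) {
    s <- seq(n, 1)
    l <- c(rep(-1, n - 1), 1)
    expect_equal(aupr_score(s, l), 1 / n)
  }
  expect_error(aupr_score(1:3, c(-1, -1, -1)), "positive")
})

test_that("AUC and AUPR agree with brute-force oracles on random tied data", {
  set.seed(41)
  for (k in 1:100) {
    n <- sample(5:50, 1)
    scores <- sample(0:6, n, replace = TRUE) / 2 # heavy ties
    labels <- sample(c(1, -1), n, replace = TRUE)
    if (!any(labels == 1) || !any(labels == -1)) next
    expect_equal(auc_score(scores, labels), auc_pairs_oracle(scores, labels),
                 tolerance = 1e-12)
    expect_equal(aupr_score(scores, labels),
                 aupr_sweep_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(42)
  scores <- rnorm(60)
  labels <- sample(c(1, -1), 60, replace = TRUE)
  expect_equal(auc_score(exp(scores), labels), auc_score(scores, labels),
               tolerance = 1e-12)
})

test_that("curve points have the documented shape", {
  set.seed(43)
  scores <- sample(1:5, 40, TRUE)
  labels <- sample(c(1, -1), 40, TRUE)
  roc <- roc_points(scores, labels)
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  pr <- pr_points(scores, labels)
  expect_true(all(diff(pr$recall) >= 0))
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
})

test_that("fold partitions are balanced, exhaustive and seeded", {
  f <- cv_folds(11, 3, seed = 7)
  expect_length(f, 11)
  expect_true(all(table(f) %in% c(3, 4)))
  expect_identical(f, cv_folds(11, 3, seed = 7))
  expect_false(identical(f, cv_folds(11, 3, seed = 8)))
  expect_error(cv_folds(5, 1), "2..n")
  expect_error(cv_folds(5, 6), "2..n")
})

test_that("k-fold blinding partitions the observed entries exactly", {
  A <- obs_matrix(matrix(c(1, 1, 1, -1), 2, 2,
                         dimnames = list(c("m1", "m2"), c("d1", "d2"))))
  res <- run_cv(A, sigma = 0.5, r = 1, scheme = "kfold", k = 2, seed = 1,
                blind = "all_observed",
                control = spg_control(max_iter = 20))
  expect_equal(res$per_fold$n_test, c(2L, 2L))
  # union of test folds = blinded set, each sample in exactly one fold
  expect_equal(as.integer(table(res$folds)), c(2L, 2L))
  expect_equal(nrow(res$blinded), 4L)
})

test_that("cross-validation is deterministic for a fixed seed", {
  sim <- make_benchmark(15, 8, 2, noise_sigma = 0.3, obs_frac = 0.9,
                        test_frac = 0, seed = 2)
  args <- list(sim$train, sigma = 0.3, r = 2, scheme = "kfold", k = 3,
               seed = 4, control = spg_control(max_iter = 60))
  r1 <- do.call(run_cv, args)
  r2 <- do.call(run_cv, args)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$folds, r2$folds)
})

test_that("pooled LOOCV ranking of held-out positives beats chance on model data", {
  sim <- make_benchmark(24, 10, 2, latent_scale = 1, noise_sigma = 0.2,
                        obs_frac = 0.6, test_frac = 0, seed = 6)
  res <- run_cv(sim$train, sigma = 0.2, r = 2, scheme = "loocv",
                blind = "positives_only",
                control = spg_control(max_iter = 80, tol = 1e-4))
  n_pos <- sum(unclass(sim$train) == 1, na.rm = TRUE)
  se <- sqrt(0.25 / n_pos)
  expect_gt(res$auc, 0.5 + 3 * se)
  # LOOCV per fold: one positive against the candidate background
  expect_equal(nrow(res$per_fold), n_pos)
})

test_that("a fold stripped of all training positives is refused", {
  A <- obs_matrix(matrix(c(1, -1, -1, -1), 2, 2,
                         dimnames = list(c("m1", "m2"), c("d1", "d2"))))
  # only one positive: blinding it leaves no positive to train on
  expect_error(run_cv(A, sigma = 0.5, r = 1, scheme = "kfold", k = 2,
                      blind = "all_observed"),
               "no training positives")
})

test_that("grid search reuses folds across cells and breaks ties deterministically", {
  sim <- make_benchmark(15, 8, 2, noise_sigma = 0.3, obs_frac = 0.9,
                        test_frac = 0, seed = 8)
  ctrl <- spg_control(max_iter = 40, tol = 1e-4)
  # duplicated cell must give the identical AUPR (fold reuse)
  tn <- tune_onebitmc(sim$train, sigmas = c(0.3, 0.3), r_ratios = 0.25,
                      control = ctrl, k = 3, seed = 1)
  expect_equal(tn$surface[1, 1], tn$surface[2, 1])
  # tie broken toward the smaller sigma
  expect_equal(tn$sigma, 0.3)

  # 1x1 grid returns that pair
  tn1 <- tune_onebitmc(sim$train, sigmas = 0.2, r_ratios = 1 / 3,
                       control = ctrl, k = 3, seed = 1)
  expect_equal(tn1$sigma, 0.2)
  expect_equal(tn1$r, max(1L, round(8 / 3)))
  expect_equal(dim(tn1$surface), c(1L, 1L))
  expect_error(tune_onebitmc(sim$train, sigmas = numeric(0)), "nonempty")
})
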