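#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic
#' \eqn{P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)} via midranks, which equals
#' the trapezoidal area under the full ROC curve with tied scores grouped
#' at one threshold. Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores numeric prediction scores.
#' @param labels labels in \{+1, -1\} (or logical / 0-1), both classes
#'   present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(y) != length(scores))
    stop("'scores' and 'labels' lengths differ", call. = FALSE)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step-curve area (average precision): precision at each
#' distinct score threshold weighted by the recall increment it produces,
#' with tied scores grouped at a single threshold. Trapezoidal
#' interpolation on PR curves is deliberately avoided (it overestimates).
#'
#' @inheritParams auc_score
#' @return AUPR in \[0, 1\]; requires at least one positive.
#' @export
aupr_score <- function(scores, labels) {
  pr <- pr_points(scores, labels)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

#' ROC curve points
#'
#' (FPR, TPR) at every distinct score threshold, descending, ties grouped;
#' starts at (0, 0) and ends at (1, 1).
#'
#' @inheritParams auc_score
#' @return data frame with columns \code{fpr}, \code{tpr}.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  g <- group_by_threshold(scores, y)
  data.frame(fpr = c(0, cumsum(g$fp) / n0), tpr = c(0, cumsum(g$tp) / n1))
}

#' Precision-recall curve points
#'
#' (recall, precision) at every distinct score threshold, descending, ties
#' grouped; recall is nondecreasing along the curve.
#'
#' @inheritParams auc_score
#' @return data frame with columns \code{recall}, \code{precision}.
#' @export
pr_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y)
  if (n1 == 0L) stop("at least one positive is required", call. = FALSE)
  g <- group_by_threshold(scores, y)
  tp <- cumsum(g$tp); fp <- cumsum(g$fp)
  data.frame(recall = tp / n1, precision = tp / (tp + fp))
}

# labels {+1,-1}, {0,1} or logical -> logical (TRUE = positive)
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  u <- unique(labels)
  if (!all(u %in% c(-1, 1)) && !all(u %in% c(0, 1)))
    stop("labels must be in {+1, -1}, {0, 1} or logical", call. = FALSE)
  labels == 1
}

# per distinct threshold (descending): counts of positives/negatives tied there
group_by_threshold <- function(scores, y) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  new_grp <- c(TRUE, s[-1L] != s[-length(s)])
  gid <- cumsum(new_grp)
  list(tp = as.vector(tapply(as.integer(y), gid, sum)),
       fp = as.vector(tapply(as.integer(!y), gid, sum)))
}

#' Cross-validation folds
#'
#' Randomly partitions \code{n} samples into \code{k} folds whose sizes
#' differ by at most one, deterministically for a given seed.
#'
#' @param n number of samples.
#' @param k number of folds (2..n); \code{k = n} is leave-one-out.
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold assignments in \code{1..k}.
#' @export
cv_folds <- function(n, k, seed = 0L) {
  if (k < 2L || k > n) stop("'k' must be in 2..n", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fold <- rep_len(seq_len(k), n)
  fold[sample.int(n)]
}

.Random.seed_save <- function()
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Cross-validated evaluation of matrix-completion predictions
#'
#' Blinds held-out entries, refits the model on the remainder, scores the
#' blinded entries with the refit latent matrix, and reports ROC/PR
#' metrics, pooled over folds and per fold.
#'
#' Two blinding schemes are supported. With \code{blind =
#' "all_observed"}, every observed entry (positive and negative) is
#' cross-validated and test labels are the entries' own \code{+1}/\code{-1}
#' values. With \code{blind = "positives_only"} (the ranking protocol used
#' when the source data records only positive associations), only
#' positives are blinded; in each fold the blinded positives are pooled
#' with the scores of every candidate pair — pairs never observed as
#' positive in the full matrix — labelled \code{-1}, so each fold yields a
#' ranking of held-out positives against the full candidate background.
#'
#' @param A an [obs_matrix].
#' @param sigma,r,r_ratio,control model settings passed to [onebitmc]
#'   (ignored for \code{method = "svd"}).
#' @param scheme \code{"kfold"} or \code{"loocv"} (k = number of blinded
#'   samples).
#' @param k number of folds for \code{"kfold"} (default 5).
#' @param seed integer seed for the fold shuffle.
#' @param blind which observed entries are blinded; see Details.
#' @param method \code{"bmc"} (probit one-bit completion) or \code{"svd"}
#'   (truncated-SVD imputation baseline).
#' @param rank,fill baseline settings for \code{method = "svd"} (rank
#'   defaults to \code{r}).
#' @param folds optional precomputed fold assignment (overrides
#'   \code{scheme}/\code{k}/\code{seed}); used to share folds across a
#'   parameter grid.
#' @return an object of class \code{"onebitmc_cv"}: pooled \code{scores}
#'   and \code{labels}, \code{auc}, \code{aupr}, \code{roc} and \code{pr}
#'   curve points, a \code{per_fold} data frame (fold, n_test, auc, aupr)
#'   and mean per-fold metrics \code{auc_fold_mean},
#'   \code{aupr_fold_mean}.
#' @export
run_cv <- function(A, sigma = 0.2, r = NULL, r_ratio = NULL,
                   control = spg_control(),
                   scheme = c("kfold", "loocv"), k = 5L, seed = 0L,
                   blind = c("positives_only", "all_observed"),
                   method = c("bmc", "svd"), rank = NULL, fill = 0,
                   folds = NULL) {
  scheme <- match.arg(scheme)
  blind <- match.arg(blind)
  method <- match.arg(method)
  if (!inherits(A, "obs_matrix")) A <- obs_matrix(as.matrix(A))
  if (!is.null(r_ratio)) {
    if (!is.null(r)) stop("give exactly one of 'r' and 'r_ratio'",
                          call. = FALSE)
    r <- max(1L, as.integer(round(r_ratio * min(dim(A)))))
  }
  a <- unclass(A)
  blinded <- if (blind == "positives_only")
    which(!is.na(a) & a == 1, arr.ind = TRUE)
  else which(!is.na(a), arr.ind = TRUE)
  blinded <- blinded[order(blinded[, 1L], blinded[, 2L]), , drop = FALSE]
  nb <- nrow(blinded)
  if (blind == "positives_only" && nb < 2L)
    stop("need at least 2 positives to cross-validate", call. = FALSE)
  if (is.null(folds)) {
    kk <- if (scheme == "loocv") nb else as.integer(k)
    folds <- cv_folds(nb, kk, seed)
  } else {
    if (length(folds) != nb) stop("'folds' length must equal the number of blinded samples", call. = FALSE)
    kk <- max(folds)
  }
  # candidate background for the ranking protocol: never-positive pairs
  cand <- which(is.na(a) | a != 1)

  scores <- labels <- numeric(0)
  per <- data.frame(fold = seq_len(kk), n_test = 0L,
                    auc = NA_real_, aupr = NA_real_)
  for (f in seq_len(kk)) {
    test_ij <- blinded[folds == f, , drop = FALSE]
    v <- a
    v[test_ij] <- NA
    if (!any(v == 1, na.rm = TRUE))
      stop("fold ", f, " has no training positives", call. = FALSE)
    A_train <- obs_matrix(v)
    X <- if (method == "bmc")
      onebitmc(A_train, sigma = sigma, r = r, control = control)$X
    else svd_impute(A_train, rank = if (is.null(rank)) r else rank,
                    fill = fill)
    if (blind == "positives_only") {
      s <- c(X[test_ij], X[cand])
      l <- c(rep(1, nrow(test_ij)), rep(-1, length(cand)))
    } else {
      s <- X[test_ij]
      l <- a[test_ij]
    }
    scores <- c(scores, s)
    labels <- c(labels, l)
    per$n_test[f] <- length(s)
    if (any(l == 1) && any(l == -1)) {
      per$auc[f] <- auc_score(s, l)
      per$aupr[f] <- aupr_score(s, l)
    }
  }
  structure(list(scores = scores, labels = labels,
                 auc = auc_score(scores, labels),
                 aupr = aupr_score(scores, labels),
                 roc = roc_points(scores, labels),
                 pr = pr_points(scores, labels),
                 per_fold = per,
                 auc_fold_mean = mean(per$auc, na.rm = TRUE),
                 aupr_fold_mean = mean(per$aupr, na.rm = TRUE),
                 folds = folds, blinded = blinded,
                 config = list(sigma = sigma, r = r, r_ratio = r_ratio,
                               scheme = scheme, k = kk, seed = seed,
                               blind = blind, method = method)),
            class = "onebitmc_cv")
}

#' @export
print.onebitmc_cv <- function(x, ...) {
  cat(sprintf("Cross-validation (%s, %d folds, blinding: %s, method: %s)\n",
              x$config$scheme, x$config$k, x$config$blind, x$config$method))
  cat(sprintf("  pooled    AUC %.4f   AUPR %.4f\n", x$auc, x$aupr))
  cat(sprintf("  fold mean AUC %.4f   AUPR %.4f\n",
              x$auc_fold_mean, x$aupr_fold_mean))
  invisible(x)
}

#' Grid search over (sigma, rank) by cross-validated AUPR
#'
#' Evaluates every combination of noise scale and rank ratio under k-fold
#' cross-validation with the same folds in every cell (so the comparison
#' is free of fold noise), and returns the pair with the highest
#' fold-averaged AUPR. AUPR is preferred over AUC as the selection
#' criterion because positives are heavily outnumbered in association
#' matrices. Ties are broken toward the smaller rank, then the smaller
#' sigma.
#'
#' @param A an [obs_matrix].
#' @param sigmas noise scales to try (default 0.1, 0.2, ..., 1.0).
#' @param r_ratios rank ratios w.r.t. \code{r_max = min(p, q)} to try
#'   (default 1/10, 1/9, ..., 1/2, 1); each maps to
#'   \code{r = max(1, round(ratio * r_max))}.
#' @param control solver settings.
#' @param k,seed,blind cross-validation settings (5-fold by default).
#' @return a list of class \code{"onebitmc_tune"}: chosen \code{sigma},
#'   \code{r_ratio}, \code{r}, its \code{aupr}, and the full AUPR
#'   \code{surface} (rows = sigmas, columns = r_ratios).
#' @export
tune_onebitmc <- function(A, sigmas = seq(0.1, 1.0, by = 0.1),
                          r_ratios = c(1 / (10:2), 1),
                          control = spg_control(), k = 5L, seed = 0L,
                          blind = c("positives_only", "all_observed")) {
  blind <- match.arg(blind)
  if (length(sigmas) == 0L || length(r_ratios) == 0L)
    stop("'sigmas' and 'r_ratios' must be nonempty", call. = FALSE)
  if (!inherits(A, "obs_matrix")) A <- obs_matrix(as.matrix(A))
  a <- unclass(A)
  nb <- if (blind == "positives_only") sum(a == 1, na.rm = TRUE)
        else sum(!is.na(a))
  folds <- cv_folds(nb, as.integer(k), seed)
  r_max <- min(dim(A))
  surface <- matrix(NA_real_, length(sigmas), length(r_ratios),
                    dimnames = list(paste0("sigma=", sigmas),
                                    paste0("ratio=", signif(r_ratios, 4))))
  for (si in seq_along(sigmas)) for (ri in seq_along(r_ratios)) {
    cv <- run_cv(A, sigma = sigmas[si], r_ratio = r_ratios[ri],
                 control = control, blind = blind, folds = folds)
    surface[si, ri] <- cv$aupr_fold_mean
  }
  rs <- vapply(r_ratios, function(x) max(1L, as.integer(round(x * r_max))),
               0L)
  # argmax with ties toward smaller r, then smaller sigma
  best <- which(surface == max(surface), arr.ind = TRUE)
  best <- best[order(rs[best[, 2L]], sigmas[best[, 1L]]), , drop = FALSE][1L, ]
  structure(list(sigma = sigmas[best[1L]], r_ratio = r_ratios[best[2L]],
                 r = rs[best[2L]], aupr = surface[best[1L], best[2L]],
                 surface = surface, folds = folds,
                 config = list(k = k, seed = seed, blind = blind)),
            class = "onebitmc_tune")
}

#' @export
print.onebitmc_tune <- function(x, ...) {
  cat(sprintf("Grid search (%d x %d cells, %d-fold CV, fold-averaged AUPR)\n",
              nrow(x$surface), ncol(x$surface), x$config$k))
  cat(sprintf("  best: sigma = %g, r = %d (ratio %.4g), AUPR %.4f\n",
              x$sigma, x$r, x$r_ratio, x$aupr))
  invisible(x)
}
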