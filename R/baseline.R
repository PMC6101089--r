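#' Truncated-SVD imputation baseline
#'
#' The simplest matrix-completion comparator: replace unknown entries by a
#' fill value, take the singular value decomposition of the completed
#' matrix, and reconstruct from the top \code{rank} components. The
#' reconstructed values at unknown positions are the prediction scores.
#'
#' @param A an [obs_matrix].
#' @param rank truncation rank, in \code{1..min(p, q)}.
#' @param fill value substituted for unknown entries before the SVD;
#'   default 0, the midpoint of the \code{+1}/\code{-1} coding
#'   (\code{-1} treats unknowns as negatives).
#' @return the rank-\code{rank} reconstruction, a \code{p x q} matrix.
#' @export
svd_impute <- function(A, rank, fill = 0) {
  if (!inherits(A, "obs_matrix")) A <- obs_matrix(as.matrix(A))
  r_max <- min(dim(A))
  if (is.null(rank) || rank < 1L || rank > r_max)
    stop("'rank' must be in 1..min(p, q) = 1..", r_max, call. = FALSE)
  v <- unclass(A)
  v[is.na(v)] <- fill
  sv <- svd(v, nu = rank, nv = rank)
  X <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
  dimnames(X) <- dimnames(A)
  X
}
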