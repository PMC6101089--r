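#' Observed binary association matrix
#'
#' Construct the partially observed \code{p x q} adjacency matrix of a
#' bipartite binary relationship. Entries are \code{+1} (association
#' observed), \code{-1} (absence observed) or \code{NA} (pair not observed).
#' The set of observed positions plays the role of the index set Omega in
#' one-bit matrix completion; \code{n_observed()} returns its cardinality m.
#'
#' @param values numeric matrix with entries in \{1, -1, NA\}; must carry
#'   row and column names (the microbe and disease identifiers).
#' @return an object of class \code{"obs_matrix"} (a classed matrix).
#' @examples
#' a <- matrix(c(1, NA, -1, 1), 2, 2,
#'             dimnames = list(c("m1", "m2"), c("d1", "d2")))
#' A <- obs_matrix(a)
#' n_observed(A)
#' @export
obs_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  bad <- !is.na(values) & values != 1 & values != -1
  if (any(bad))
    stop("entries must be +1, -1 or NA; found ",
         values[which(bad)[1L]], call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("r", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate row identifiers", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate column identifiers", call. = FALSE)
  structure(values, class = c("obs_matrix", "matrix"))
}

#' @rdname obs_matrix
#' @param x an \code{obs_matrix}.
#' @export
n_observed <- function(x) sum(!is.na(unclass(x)))

#' Observed index set
#'
#' Positions of the observed entries (Omega) as a two-column matrix of
#' (row, column) indices, in column-major order.
#'
#' @param x an \code{obs_matrix}.
#' @return integer matrix with columns \code{i}, \code{j}.
#' @export
observed_index <- function(x) {
  ij <- which(!is.na(unclass(x)), arr.ind = TRUE)
  dimnames(ij) <- list(NULL, c("i", "j"))
  ij[order(ij[, 2L], ij[, 1L]), , drop = FALSE]
}

#' @export
print.obs_matrix <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("Observed binary matrix: %d x %d, %d observed (%d positive, %d negative)\n",
              nrow(v), ncol(v), sum(!is.na(v)),
              sum(v == 1, na.rm = TRUE), sum(v == -1, na.rm = TRUE)))
  if (nrow(v) <= 10 && ncol(v) <= 10) print(v) else
    cat("  (use unclass() to inspect entries)\n")
  invisible(x)
}

# internal: validate conformability of a latent matrix with an obs_matrix
check_conformable <- function(X, A) {
  if (!is.matrix(X) || any(dim(X) != dim(A)))
    stop("latent matrix is not conformable with the observed matrix",
         call. = FALSE)
  if (!all(is.finite(X)))
    stop("latent matrix has non-finite entries", call. = FALSE)
  invisible(TRUE)
}
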