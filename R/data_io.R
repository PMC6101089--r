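#' Read a long-format association list
#'
#' Reads a TSV/CSV file with columns \code{microbe_id}, \code{disease_id}
#' and an optional \code{label} column (+1/-1; missing column means every
#' record is a positive association) and assembles the partially observed
#' adjacency matrix. Rows are microbes, columns diseases, both in order of
#' first appearance in the file.
#'
#' Pairs not listed in the file are handled by \code{unknown}:
#' \describe{
#'   \item{\code{"negative"}}{unlisted pairs become observed \code{-1};
#'     every cell is then in Omega. This is the default, matching
#'     ranking-based evaluation against all non-positive pairs when the
#'     source database records only positives.}
#'   \item{\code{"missing"}}{unlisted pairs stay unknown (\code{NA}).}
#' }
#'
#' @param path path to a TSV (default) or CSV file with a header line.
#' @param unknown policy for pairs absent from the file.
#' @param sep field separator; guessed from the file extension when NULL
#'   (".csv" means comma, anything else tab).
#' @return an [obs_matrix].
#' @details Accepted labels are \code{1}, \code{+1} and \code{-1}. A
#'   \code{0} label is refused: it is ambiguous between "observed negative"
#'   and "unknown". Duplicate pairs with identical labels collapse to one
#'   record; duplicates with conflicting labels are an error.
#' @export
read_association_list <- function(path, unknown = c("negative", "missing"),
                                  sep = NULL) {
  unknown <- match.arg(unknown)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("microbe_id", "disease_id")
  if (!all(need %in% names(df)))
    stop("header must contain columns 'microbe_id' and 'disease_id'",
         call. = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path, call. = FALSE)
  if ("label" %in% names(df)) {
    lab_chr <- trimws(df$label)
    ok <- lab_chr %in% c("1", "+1", "-1")
    if (!all(ok))
      stop(sprintf("malformed label '%s' at line %d of %s (allowed: 1, +1, -1)",
                   lab_chr[which(!ok)[1L]], which(!ok)[1L] + 1L, path),
           call. = FALSE)
    lab <- ifelse(lab_chr == "-1", -1, 1)
  } else lab <- rep(1, nrow(df))

  rows <- unique(df$microbe_id)
  cols <- unique(df$disease_id)
  key <- paste(df$microbe_id, df$disease_id, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(lab, key, function(l) length(unique(l)))
    if (any(agg > 1L)) {
      bad <- names(agg)[agg > 1L][1L]
      stop("conflicting labels for pair ",
           gsub("\r", " / ", bad, fixed = TRUE), call. = FALSE)
    }
    keep <- !duplicated(key)
    df <- df[keep, , drop = FALSE]
    lab <- lab[keep]
  }

  fill <- if (unknown == "negative") -1 else NA_real_
  v <- matrix(fill, length(rows), length(cols),
              dimnames = list(rows, cols))
  v[cbind(match(df$microbe_id, rows), match(df$disease_id, cols))] <- lab
  obs_matrix(v)
}

#' Write an association list
#'
#' Serializes the observed entries of an [obs_matrix] back to a long-format
#' TSV (columns \code{microbe_id}, \code{disease_id}, \code{label}), the
#' inverse of [read_association_list] with \code{unknown = "missing"}.
#'
#' @param x an [obs_matrix].
#' @param path output path.
#' @export
write_association_list <- function(x, path) {
  ij <- observed_index(x)
  df <- data.frame(microbe_id = rownames(x)[ij[, 1L]],
                   disease_id = colnames(x)[ij[, 2L]],
                   label = unclass(x)[ij],
                   stringsAsFactors = FALSE)
  df <- df[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  utils::write.table(format(df, scientific = FALSE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense +1/-1/unknown matrix
#'
#' TSV dialect: header row holds the column (disease) identifiers, the first
#' column holds the row (microbe) identifiers, cells are \code{1},
#' \code{-1}, or \code{NA}/empty for unknown.
#'
#' @param path input TSV path.
#' @return an [obs_matrix]; \code{NA}/empty cells are excluded from Omega.
#' @export
read_dense_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("empty data section in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1L]]
  body <- parts[-1L]
  widths <- lengths(body)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in ", path, call. = FALSE)
  q <- widths[1L] - 1L
  if (q < 1L) stop("empty data section in ", path, call. = FALSE)
  # header may or may not carry a stub for the id column
  cols <- if (length(header) == q + 1L) header[-1L] else header
  if (length(cols) != q)
    stop("ragged rows in ", path, call. = FALSE)
  rows <- vapply(body, `[[`, "", 1L)
  cell <- function(s) {
    s <- trimws(s)
    if (s == "" || s == "NA") return(NA_real_)
    if (s %in% c("1", "+1")) return(1)
    if (s == "-1") return(-1)
    stop("cell value '", s, "' not in {1, -1, NA}", call. = FALSE)
  }
  v <- matrix(NA_real_, length(body), q)
  for (b in seq_along(body))
    v[b, ] <- vapply(body[[b]][-1L], cell, 0, USE.NAMES = FALSE)
  dimnames(v) <- list(rows, cols)
  obs_matrix(v)
}

#' Write a dense +1/-1/unknown matrix
#'
#' Inverse of [read_dense_matrix]; unknown entries are written as \code{NA}.
#'
#' @param x an [obs_matrix].
#' @param path output TSV path.
#' @export
write_dense_matrix <- function(x, path) {
  v <- unclass(x)
  lines <- c(paste(c("id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i],
                       ifelse(is.na(v[i, ]), "NA",
                              format(v[i, ], scientific = FALSE,
                                     trim = TRUE))),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked score table
#'
#' Writes predicted scores as a TSV of
#' \code{microbe_id  disease_id  score  observed}, sorted by score
#' descending; ties are broken by (row index, column index) ascending so the
#' output is deterministic. Scores are printed at 6 significant digits.
#'
#' @param X real score matrix conformable with \code{observed}.
#' @param observed the [obs_matrix] the scores refer to.
#' @param path output TSV path.
#' @param top_k number of rows to keep (default all).
#' @export
write_score_table <- function(X, observed, path, top_k = Inf) {
  check_conformable(X, observed)
  p <- nrow(X); q <- ncol(X)
  i <- rep(seq_len(p), times = q)
  j <- rep(seq_len(q), each = p)
  s <- as.vector(X)
  ord <- order(-s, i, j)
  keep <- ord[seq_len(min(top_k, length(ord)))]
  df <- data.frame(microbe_id = rownames(observed)[i[keep]],
                   disease_id = colnames(observed)[j[keep]],
                   score = sprintf("%.6g", s[keep]),
                   observed = as.integer(!is.na(unclass(observed)[cbind(i[keep], j[keep])])),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
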