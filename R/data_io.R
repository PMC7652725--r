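#' Construct a microbe-disease association dataset
#'
#' Bundles an ordered microbe label vector, an ordered disease label vector
#' and the binary association matrix `Y` (rows = microbes, columns =
#' diseases; `Y[i, j] = 1` means microbe i is a known associate of disease
#' j).
#'
#' @param microbes character vector of unique microbe labels (length n).
#' @param diseases character vector of unique disease labels (length m).
#' @param Y n x m binary matrix of known associations.
#' @return An object of class `mda_dataset`: a list with elements
#'   `microbes`, `diseases`, `Y` (with dimnames set from the labels).
#' @export
mda_dataset <- function(microbes, diseases, Y) {
  microbes <- as.character(microbes)
  diseases <- as.character(diseases)
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (anyDuplicated(microbes)) stop("duplicated microbe labels")
  if (anyDuplicated(diseases)) stop("duplicated disease labels")
  if (nrow(Y) != length(microbes) || ncol(Y) != length(diseases)) {
    stop("Y dimensions do not match label lengths")
  }
  if (!all(Y %in% c(0, 1))) stop("Y must be binary (0/1)")
  if (sum(Y) == 0) stop("Y has no known associations")
  dimnames(Y) <- list(microbes, diseases)
  structure(list(microbes = microbes, diseases = diseases, Y = Y),
            class = "mda_dataset")
}

#' @export
print.mda_dataset <- function(x, ...) {
  cat(sprintf("mda_dataset: %d microbes x %d diseases, %d known associations (density %.4f)\n",
              length(x$microbes), length(x$diseases), sum(x$Y),
              mean(x$Y)))
  invisible(x)
}

#' Read a microbe-disease association table
#'
#' Reads a tab-separated pair list (microbe label, disease label, one pair
#' per row; extra columns ignored; lines starting with `#` skipped) into an
#' [mda_dataset()]. Labels keep their order of first appearance; surrounding
#' whitespace is trimmed but case is preserved.
#'
#' @param path path to the TSV file.
#' @param dedup collapse repeated (microbe, disease) pairs to a single
#'   association (default `TRUE`); the number of dropped duplicates is
#'   reported via `message()`.
#' @return An `mda_dataset`.
#' @export
read_association_table <- function(path, dedup = TRUE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) stop("empty association table: ", path)
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("malformed row at line %d of %s: expected >= 2 tab-separated fields",
                 rows[which(nf < 2L)[1L]], path))
  }
  mic <- trimws(vapply(fields, `[[`, "", 1L))
  dis <- trimws(vapply(fields, `[[`, "", 2L))
  if (any(mic == "") || any(dis == "")) {
    bad <- which(mic == "" | dis == "")[1L]
    stop(sprintf("malformed row at line %d of %s: empty label", rows[bad], path))
  }
  pairs <- paste(mic, dis, sep = "\r")
  if (dedup) {
    dup <- duplicated(pairs)
    if (any(dup)) message(sum(dup), " duplicate association(s) dropped")
    mic <- mic[!dup]
    dis <- dis[!dup]
  }
  microbes <- unique(mic)
  diseases <- unique(dis)
  Y <- matrix(0, length(microbes), length(diseases))
  Y[cbind(match(mic, microbes), match(dis, diseases))] <- 1
  mda_dataset(microbes, diseases, Y)
}

#' Write an association dataset back to a pair-list TSV
#'
#' Inverse of [read_association_table()]: one (microbe, disease) row per
#' known association, ordered by (microbe index, disease index).
#'
#' @param dataset an `mda_dataset`.
#' @param path output path.
#' @export
write_association_table <- function(dataset, path) {
  idx <- which(dataset$Y == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(microbe = dataset$microbes[idx[, 1L]],
                   disease = dataset$diseases[idx[, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a labeled numeric matrix (similarity or disease x symptom)
#'
#' Expects a TSV with a header row of column labels and a first column of
#' row labels. When `similarity = TRUE` the matrix must be square with
#' matching row/column labels and symmetric within `1e-10`.
#'
#' @param path path to the TSV file.
#' @param similarity validate the matrix as a similarity matrix.
#' @return A labeled numeric matrix.
#' @export
read_matrix <- function(path, similarity = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE, comment.char = "#",
                          colClasses = NA)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("non-numeric cell in matrix file: ", path)
  if (anyDuplicated(rownames(M))) stop("duplicated row labels in ", path)
  if (anyDuplicated(colnames(M))) stop("duplicated column labels in ", path)
  if (similarity) validate_similarity(M)
  M
}

#' Validate a similarity matrix contract
#'
#' Checks squareness, matching labels, symmetry (tolerance `1e-10`) and
#' nonnegativity. Returns the matrix invisibly so it can be used in
#' pipelines.
#'
#' @param S numeric matrix.
#' @keywords internal
validate_similarity <- function(S) {
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (!is.null(rownames(S)) && !is.null(colnames(S)) &&
      !identical(rownames(S), colnames(S))) {
    stop("similarity matrix row/column labels differ")
  }
  if (max(abs(S - t(S))) > 1e-10) stop("similarity matrix is not symmetric")
  if (any(S < 0)) stop("similarity matrix has negative entries")
  invisible(S)
}

#' Rank and write association predictions
#'
#' Produces a four-column TSV (microbe, disease, score, rank) sorted by
#' score descending; ties are broken by (microbe index, disease index)
#' ascending so output is fully deterministic. With `mask_known = TRUE`
#' pairs already present in the dataset are omitted, leaving only candidate
#' associations.
#'
#' @param scores n x m numeric score matrix, same shape as `dataset$Y`.
#' @param dataset an `mda_dataset`.
#' @param path output path, or `NULL` to return the data frame only.
#' @param mask_known drop known-positive pairs (default `TRUE`).
#' @return Invisibly, the ranked data frame.
#' @export
write_ranked_predictions <- function(scores, dataset, path = NULL,
                                     mask_known = TRUE) {
  scores <- as.matrix(scores)
  if (!all(dim(scores) == dim(dataset$Y))) {
    stop("score matrix shape does not match dataset")
  }
  keep <- if (mask_known) which(dataset$Y == 0, arr.ind = TRUE)
          else arrayInd(seq_along(scores), dim(scores))
  s <- scores[keep]
  ord <- order(-s, keep[, 1L], keep[, 2L])
  df <- data.frame(
    microbe = dataset$microbes[keep[ord, 1L]],
    disease = dataset$diseases[keep[ord, 2L]],
    score = s[ord],
    rank = seq_along(ord)
  )
  if (!is.null(path)) {
    utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
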