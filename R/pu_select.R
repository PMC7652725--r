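#' Spy-based selection of reliable negative pairs
#'
#' Positive-unlabeled learning step: a random subset of known positives
#' (the "spies") is temporarily relabeled as unlabeled, the random walk
#' with restart is run on the spy-depleted network, and the minimum walk
#' score attained by any spy (`am_min`) becomes the reliability threshold —
#' every unlabeled pair scoring strictly below it is a candidate reliable
#' negative. Candidates are then truncated to `round(nmdar * |P|)` pairs,
#' keeping the lowest scores.
#'
#' @param dataset an [mda_dataset()] with at least 2 positives.
#' @param SM,SD microbe and disease similarity matrices (typically GAP /
#'   fused similarities computed from the training matrix).
#' @param spy_fraction fraction of positives used as spies, in (0, 1);
#'   default 0.1. At least one spy is always drawn.
#' @param nmdar ratio of selected negatives to known positives (>= 0);
#'   default 1. `nmdar = 0` returns an empty set.
#' @param seed RNG seed for the spy draw.
#' @param repeats number of independent spy rounds; with `repeats > 1` the
#'   walk scores and the threshold are averaged across rounds (default 1).
#' @param exclude optional n x m logical matrix; `TRUE` pairs (e.g. held-out
#'   test pairs) are never selected as negatives.
#' @param lambda_jump,theta,eta,tol,max_iter,mode random-walk settings, see
#'   [score_all_pairs()].
#' @param score_fn scoring engine: a `function(Y_depleted)` returning an
#'   n x m score matrix. Defaults to the random walk with restart on the
#'   heterogeneous network; injectable for testing the thresholding steps
#'   in isolation.
#' @return An object of class `negative_set`: list with `pairs` (k x 2
#'   index matrix), `scores` (walk scores, ascending), `am_min` (spy
#'   threshold), `fallback` (logical: threshold selection failed and the
#'   globally lowest-scoring unlabeled pairs were used instead).
#' @export
select_reliable_negatives <- function(dataset, SM, SD,
                                      spy_fraction = 0.1, nmdar = 1,
                                      seed = NULL, repeats = 1L,
                                      exclude = NULL,
                                      lambda_jump = 0.9, theta = 0.5,
                                      eta = 0.9, tol = 1e-11,
                                      max_iter = 10000L, mode = "disease",
                                      score_fn = NULL) {
  if (spy_fraction <= 0 || spy_fraction >= 1) stop("spy_fraction must be in (0, 1)")
  if (nmdar < 0) stop("nmdar must be >= 0")
  Y <- dataset$Y
  pos <- which(Y == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (n_pos == 0L) stop("dataset has no positive associations")
  if (n_pos < 2L) stop("need at least 2 positives to plant spies")
  if (nmdar == 0) {
    return(structure(list(pairs = matrix(integer(0), 0, 2),
                          scores = numeric(0), am_min = NA_real_,
                          fallback = FALSE),
                     class = "negative_set"))
  }
  if (!is.null(seed)) set.seed(seed)
  n_spies <- max(1L, round(spy_fraction * n_pos))

  AM_acc <- matrix(0, nrow(Y), ncol(Y))
  am_min_acc <- 0
  spy_mask <- matrix(FALSE, nrow(Y), ncol(Y))
  for (rep in seq_len(repeats)) {
    spy_idx <- sample.int(n_pos, n_spies)
    spies <- pos[spy_idx, , drop = FALSE]
    spy_mask[spies] <- TRUE
    Y_dep <- Y
    Y_dep[spies] <- 0
    AM <- if (is.null(score_fn)) {
      score_all_pairs(SM, SD, Y_dep, lambda_jump = lambda_jump,
                      theta = theta, eta = eta, tol = tol,
                      max_iter = max_iter, mode = mode)
    } else {
      score_fn(Y_dep)
    }
    AM_acc <- AM_acc + AM
    am_min_acc <- am_min_acc + min(AM[spies])
  }
  AM <- AM_acc / repeats
  am_min <- am_min_acc / repeats

  eligible <- Y == 0 & !spy_mask
  if (!is.null(exclude)) eligible <- eligible & !exclude
  cand <- which(eligible & AM < am_min, arr.ind = TRUE)
  fallback <- FALSE
  if (nrow(cand) == 0L) {
    warning("no unlabeled pair scores below the spy threshold; ",
            "falling back to the globally lowest-scoring unlabeled pairs")
    fallback <- TRUE
    cand <- which(eligible, arr.ind = TRUE)
  }
  rn <- structure(list(pairs = unname(cand), scores = AM[cand],
                       am_min = am_min, fallback = fallback),
                  class = "negative_set")
  truncate_to_ratio(rn, n_pos, nmdar)
}

#' Truncate a negative set to the target negative:positive ratio
#'
#' Keeps the `round(nmdar * n_positives)` lowest-scoring pairs (most
#' reliably negative); ties at the cut are broken by (microbe, disease)
#' index order. If fewer candidates exist than requested, all are kept and
#' a shortfall warning is raised.
#'
#' @param rn a `negative_set`.
#' @param n_positives number of known positive associations.
#' @param nmdar target ratio of negatives to positives (>= 0).
#' @return The truncated `negative_set`, scores ascending.
#' @export
truncate_to_ratio <- function(rn, n_positives, nmdar) {
  if (nmdar < 0) stop("nmdar must be >= 0")
  want <- round(nmdar * n_positives)
  ord <- order(rn$scores, rn$pairs[, 1L], rn$pairs[, 2L])
  if (length(ord) < want) {
    warning(sprintf("only %d reliable negatives available (%d requested)",
                    length(ord), want))
    want <- length(ord)
  }
  keep <- ord[seq_len(want)]
  structure(list(pairs = rn$pairs[keep, , drop = FALSE],
                 scores = rn$scores[keep],
                 am_min = rn$am_min, fallback = rn$fallback),
            class = "negative_set")
}

#' @export
print.negative_set <- function(x, ...) {
  cat(sprintf("negative_set: %d pairs, spy threshold %.4g%s\n",
              nrow(x$pairs), x$am_min,
              if (isTRUE(x$fallback)) " (fallback selection)" else ""))
  invisible(x)
}

#' Write a negative set as a three-column TSV
#'
#' @param rn a `negative_set`.
#' @param dataset the `mda_dataset` providing the labels.
#' @param path output path.
#' @export
write_negative_set <- function(rn, dataset, path) {
  df <- data.frame(microbe = dataset$microbes[rn$pairs[, 1L]],
                   disease = dataset$diseases[rn$pairs[, 2L]],
                   score = rn$scores)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
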