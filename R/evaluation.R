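# Cross-validation harness. Three masking schemes on the binary matrix Y:
#   cv1 - whole microbes (rows) held out: "new microbe" setting
#   cv2 - whole diseases (columns) held out: "new disease" setting
#   cv3 - individual pairs (entries) held out: "new pair" setting
# Every fold recomputes similarities from its own training matrix, so no
# held-out signal leaks into the kernels, the walk, the negative selection
# or the factorization.

#' Build cross-validation folds
#'
#' Partitions the masked axis (rows for `"cv1"`, columns for `"cv2"`,
#' entries for `"cv3"`) into `folds` near-equal groups. Each fold's test
#' units are zeroed in that fold's training matrix; all pairs in a masked
#' row/column (or the masked entries themselves for cv3) become test pairs,
#' with their original values as labels.
#'
#' @param dataset an [mda_dataset()].
#' @param scheme `"cv1"`, `"cv2"`, or `"cv3"`.
#' @param folds number of folds (default 5).
#' @param seed RNG seed for the partition.
#' @return List of folds; each fold is a list with `train_Y` (n x m
#'   matrix), `test_idx` (k x 2 index matrix) and `test_labels` (binary
#'   vector).
#' @export
make_folds <- function(dataset, scheme = c("cv3", "cv1", "cv2"), folds = 5L,
                       seed = NULL) {
  scheme <- match.arg(scheme)
  Y <- dataset$Y
  n <- nrow(Y); m <- ncol(Y)
  n_units <- switch(scheme, cv1 = n, cv2 = m, cv3 = n * m)
  if (n_units < folds) stop("fewer units than folds on the masked axis")
  if (!is.null(seed)) set.seed(seed)
  assignment <- sample(rep_len(seq_len(folds), n_units))
  lapply(seq_len(folds), function(f) {
    train_Y <- Y
    if (scheme == "cv1") {
      rows <- which(assignment == f)
      train_Y[rows, ] <- 0
      test_idx <- as.matrix(expand.grid(i = rows, j = seq_len(m)))
    } else if (scheme == "cv2") {
      cols <- which(assignment == f)
      train_Y[, cols] <- 0
      test_idx <- as.matrix(expand.grid(i = seq_len(n), j = cols))
    } else {
      ent <- which(assignment == f)
      test_idx <- arrayInd(ent, dim(Y))
      train_Y[ent] <- 0
    }
    dimnames(test_idx) <- NULL
    colnames(test_idx) <- c("i", "j")
    list(train_Y = train_Y, test_idx = test_idx,
         test_labels = Y[test_idx])
  })
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outranks a random negative, with
#' ties counted 1/2 — computed from midranks, no curve construction.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (0/1), same length.
#' @return AUC in \[0, 1\], or `NA` if only one class is present.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Predicts class 1 when `score >= threshold` and reports sensitivity
#' (TP / (TP + FN)), specificity (TN / (TN + FP)) and accuracy.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (0/1).
#' @param threshold decision threshold (default 0.5).
#' @return Named numeric vector `c(sensitivity, specificity, accuracy)`;
#'   sensitivity/specificity are `NA` when their class is absent.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels > 0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(labels))
}

#' Score one training matrix with the full pipeline
#'
#' Internal engine shared by [run_cv()] and [run_predict()]: computes GAP
#' similarities from `train_Y`, fuses optional symptom similarity, selects
#' reliable negatives by the spy procedure (unless `config$nmdar == 0`),
#' fits the factorization, smooths cold entities, and returns the n x m
#' probability matrix.
#'
#' @param train_Y binary training matrix.
#' @param config an [mda_config()] list.
#' @param symptom optional disease x symptom matrix.
#' @param exclude optional logical matrix of pairs excluded from training
#'   (held-out test pairs).
#' @param seed RNG seed controlling spy draw and factor initialization.
#' @param shuffle_similarities permute entity labels of both similarity
#'   matrices before use (degenerate control for testing that the kernels
#'   carry signal).
#' @return List with `scores` (probability matrix), `negatives`, `factors`,
#'   and the similarity matrices used.
#' @export
pipeline_scores <- function(train_Y, config = mda_config(), symptom = NULL,
                            exclude = NULL, seed = 1L,
                            shuffle_similarities = FALSE) {
  n <- nrow(train_Y); m <- ncol(train_Y)
  SM <- gap_similarity(train_Y, config$gamma_m_prime)
  SG <- gap_similarity(t(train_Y), config$gamma_d_prime)
  SS <- if (!is.null(symptom)) symptom_similarity(symptom) else NULL
  SD <- fuse_disease_similarity(SG, SS, config$gamma_fuse)
  if (shuffle_similarities) {
    set.seed(seed + 211L)
    pm <- sample.int(n); pd <- sample.int(m)
    SM <- SM[pm, pm]
    SD <- SD[pd, pd]
  }
  negatives <- NULL
  if (config$nmdar > 0) {
    negatives <- select_reliable_negatives(
      mda_dataset(sprintf("m%d", seq_len(n)), sprintf("d%d", seq_len(m)), train_Y),
      SM, SD,
      spy_fraction = config$spy_fraction, nmdar = config$nmdar,
      seed = seed + 97L, repeats = config$pu_repeats, exclude = exclude,
      lambda_jump = config$lambda_jump, theta = config$theta,
      eta = config$eta, tol = config$rwr_tol,
      max_iter = config$rwr_max_iter, mode = config$rwr_mode)
  }
  W <- build_training_weights(train_Y, negatives, config$c_weight, exclude)
  factors <- nrlmf_fit(train_Y, W, SM, SD, rank = config$rank,
                       c_weight = config$c_weight,
                       lambda_m = config$lambda_m, lambda_d = config$lambda_d,
                       alpha = config$alpha, knn = config$knn,
                       learning_rate = config$learning_rate,
                       max_iter = config$max_iter, seed = seed + 7L)
  smoothed <- FALSE
  trained_m <- rowSums(train_Y) > 0
  trained_d <- colSums(train_Y) > 0
  if (any(!trained_m) || any(!trained_d)) {
    factors <- neighbor_smooth_cold(factors, SM, SD, trained_m, trained_d)
    smoothed <- TRUE
  }
  list(scores = predict_association(factors), negatives = negatives,
       factors = factors, SM = SM, SD = SD, cold_smoothed = smoothed)
}

#' Run cross-validated evaluation of the full pipeline
#'
#' For each repeat and fold: recompute similarities from the fold's
#' training matrix, run negative selection (held-out pairs are never
#' eligible as training negatives), fit the factorization, smooth cold
#' entities, score the test pairs, and record AUC plus thresholded
#' sensitivity/specificity/accuracy. Folds whose test set lacks positives
#' (or negatives) contribute no AUC and are counted in `n_undefined_auc`.
#'
#' @param dataset an [mda_dataset()].
#' @param config an [mda_config()] list.
#' @param scheme `"cv1"`, `"cv2"`, or `"cv3"`.
#' @param folds folds per repeat (default 5).
#' @param repeats number of repeated partitions (default 1).
#' @param seed base RNG seed; repeat t uses `seed + t`.
#' @param symptom optional disease x symptom matrix.
#' @param shuffle_similarities degenerate control, see [pipeline_scores()].
#' @return List of class `cv_report`: per-fold data frame `folds`, grand
#'   `means` (sensitivity, specificity, accuracy, auc), `scheme`,
#'   `n_undefined_auc`.
#' @export
run_cv <- function(dataset, config = mda_config(), scheme = "cv3",
                   folds = 5L, repeats = 1L, seed = 1L, symptom = NULL,
                   shuffle_similarities = FALSE) {
  rows <- list()
  n_undef <- 0L
  for (rep_i in seq_len(repeats)) {
    plan <- make_folds(dataset, scheme, folds, seed = seed + rep_i)
    for (f in seq_along(plan)) {
      fold <- plan[[f]]
      exclude <- matrix(FALSE, nrow(dataset$Y), ncol(dataset$Y))
      exclude[fold$test_idx] <- TRUE
      res <- pipeline_scores(fold$train_Y, config, symptom = symptom,
                             exclude = exclude,
                             seed = seed * 1000L + rep_i * 10L + f,
                             shuffle_similarities = shuffle_similarities)
      s <- res$scores[fold$test_idx]
      a <- auc_score(s, fold$test_labels)
      if (is.na(a)) n_undef <- n_undef + 1L
      tm <- threshold_metrics(s, fold$test_labels, config$threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = rep_i, fold = f, auc = a,
        sensitivity = tm[["sensitivity"]],
        specificity = tm[["specificity"]],
        accuracy = tm[["accuracy"]])
    }
  }
  df <- do.call(rbind, rows)
  means <- c(sensitivity = mean(df$sensitivity, na.rm = TRUE),
             specificity = mean(df$specificity, na.rm = TRUE),
             accuracy = mean(df$accuracy, na.rm = TRUE),
             auc = mean(df$auc, na.rm = TRUE))
  if (n_undef > 0L) {
    warning(n_undef, " fold(s) had a single-class test set; dropped from the AUC mean")
  }
  structure(list(folds = df, means = means, scheme = scheme,
                 n_folds = folds, repeats = repeats, seed = seed,
                 n_undefined_auc = n_undef),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%s, %d x %d folds): AUC %.4f, sens %.4f, spec %.4f, acc %.4f\n",
              x$scheme, x$repeats, x$n_folds, x$means[["auc"]],
              x$means[["sensitivity"]], x$means[["specificity"]],
              x$means[["accuracy"]]))
  invisible(x)
}
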