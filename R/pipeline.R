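# End-to-end orchestration: configuration defaults, whole-matrix
# prediction, and the negative-ratio sweep. The command-line wrapper in
# inst/cli/mdapred.R is a thin layer over these functions.

#' Pipeline configuration with the model's default hyperparameters
#'
#' Defaults follow the grid-searched operating point of the method:
#' `lambda_jump = 0.9`, `theta = 0.5`, `eta = 0.9`, `c_weight = 8`,
#' `knn = 5`, GAP bandwidths `gamma_m_prime = gamma_d_prime = 1`, symptom
#' fusion weight `gamma_fuse = 0.9`, negative:positive ratio `nmdar = 1`,
#' RWR tolerance `1e-11`. Factorization controls (`rank = 20`,
#' `lambda_m = lambda_d = 0.125`, `alpha = 0.25`, `learning_rate = 0.1`,
#' `max_iter = 100`) follow standard neighborhood-regularized logistic MF
#' practice.
#'
#' @param ... named overrides of any default.
#' @return Named list of class `mda_config`.
#' @export
mda_config <- function(...) {
  cfg <- list(
    gamma_m_prime = 1, gamma_d_prime = 1, gamma_fuse = 0.9,
    lambda_jump = 0.9, theta = 0.5, eta = 0.9,
    rwr_tol = 1e-11, rwr_max_iter = 10000L, rwr_mode = "disease",
    spy_fraction = 0.1, nmdar = 1, pu_repeats = 1L,
    rank = 20L, c_weight = 8, lambda_m = 0.125, lambda_d = 0.125,
    alpha = 0.25, knn = 5L, learning_rate = 0.1, max_iter = 100L,
    threshold = 0.5
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown config field(s): ",
                              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg$defaulted <- setdiff(names(cfg), c(names(over), "defaulted"))
  structure(cfg, class = "mda_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' File values override package defaults; fields absent from the file keep
#' their defaults (and are flagged in `$defaulted`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file of config fields.
#' @return An [mda_config()] list.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(mda_config, vals)
}

#' Predict association candidates for a complete dataset
#'
#' Runs the full pipeline (similarities, random walk, spy-based negative
#' selection, factorization) on the whole association matrix and ranks the
#' unknown pairs by predicted probability.
#'
#' @param dataset an [mda_dataset()].
#' @param config an [mda_config()] list.
#' @param symptom optional disease x symptom matrix (row order matching
#'   `dataset$diseases`).
#' @param seed RNG seed (spy draw + factor initialization).
#' @param path optional output TSV path for the ranked candidate pairs.
#' @return List with `predictions` (ranked data frame of unknown pairs),
#'   `scores` (full probability matrix), and `metadata` (parameters, seed,
#'   negative-selection summary, warnings flags).
#' @export
run_predict <- function(dataset, config = mda_config(), symptom = NULL,
                        seed = 1L, path = NULL) {
  res <- pipeline_scores(dataset$Y, config, symptom = symptom, seed = seed)
  preds <- write_ranked_predictions(res$scores, dataset, path = path,
                                    mask_known = TRUE)
  metadata <- list(
    parameters = unclass(config)[setdiff(names(config), "defaulted")],
    defaulted = config$defaulted,
    seed = seed,
    n_microbes = length(dataset$microbes),
    n_diseases = length(dataset$diseases),
    n_positives = sum(dataset$Y),
    rwr_mode = config$rwr_mode,
    negatives_mode = if (config$nmdar > 0) "spy-selected" else "all-unlabeled",
    n_negatives = if (!is.null(res$negatives)) nrow(res$negatives$pairs) else NA,
    pu_fallback = isTRUE(res$negatives$fallback),
    cold_smoothed = res$cold_smoothed
  )
  list(predictions = preds, scores = res$scores, metadata = metadata)
}

#' Sweep the negative:positive selection ratio
#'
#' Re-runs cross-validation at each requested ratio with shared folds and
#' seeds (only `nmdar` varies), producing one metric row per ratio — the
#' standard design for asking whether reliable-negative selection helps at
#' all and how much of it to use.
#'
#' @param dataset an [mda_dataset()].
#' @param config base [mda_config()]; its `nmdar` is overridden.
#' @param ratios numeric vector of nonnegative ratios.
#' @param scheme,folds,repeats,seed,symptom as in [run_cv()].
#' @return Data frame with columns `nmdar`, `sensitivity`, `specificity`,
#'   `accuracy`, `auc`.
#' @export
run_nmdar_sweep <- function(dataset, config = mda_config(),
                            ratios = c(0, 0.5, 1, 2), scheme = "cv3",
                            folds = 5L, repeats = 1L, seed = 1L,
                            symptom = NULL) {
  if (any(ratios < 0)) stop("ratios must be >= 0")
  rows <- lapply(ratios, function(r) {
    cfg <- config
    cfg$nmdar <- r
    rep <- run_cv(dataset, cfg, scheme = scheme, folds = folds,
                  repeats = repeats, seed = seed, symptom = symptom)
    data.frame(nmdar = r,
               sensitivity = rep$means[["sensitivity"]],
               specificity = rep$means[["specificity"]],
               accuracy = rep$means[["accuracy"]],
               auc = rep$means[["auc"]])
  })
  do.call(rbind, rows)
}
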