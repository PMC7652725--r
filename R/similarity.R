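#' Gaussian association-profile (GAP) kernel similarity
#'
#' RBF kernel between binary association profiles with a profile-norm
#' normalized bandwidth: `S(i, j) = exp(-gamma * ||AP_i - AP_j||^2)` with
#' `gamma = gamma_prime / mean_k(||AP_k||^2)`. Applied to the rows of the
#' association matrix it yields microbe similarity; applied to the columns
#' it yields the disease GAP similarity.
#'
#' @param profiles k x p binary matrix whose rows are association profiles.
#' @param gamma_prime positive bandwidth parameter (default 1).
#' @return k x k symmetric similarity matrix with unit diagonal and entries
#'   in (0, 1], labeled from `rownames(profiles)` if present.
#' @export
gap_similarity <- function(profiles, gamma_prime = 1) {
  profiles <- as.matrix(profiles)
  if (gamma_prime <= 0) stop("gamma_prime must be > 0")
  sq_norms <- rowSums(profiles^2)
  mean_norm <- mean(sq_norms)
  if (mean_norm == 0) {
    stop("all association profiles are zero: GAP bandwidth undefined")
  }
  gamma <- gamma_prime / mean_norm
  # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b, clipped at 0 for fp safety
  d2 <- outer(sq_norms, sq_norms, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  S <- exp(-gamma * d2)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  S
}

#' Cosine similarity between disease symptom profiles
#'
#' Each disease is described by a nonnegative symptom weight vector (raw
#' counts or pre-computed TF-IDF weights; no re-weighting is applied).
#' All-zero rows get similarity 0 to every other disease and 1 to
#' themselves, avoiding a 0/0.
#'
#' @param disease_symptom m x q nonnegative matrix (rows = diseases).
#' @return m x m symmetric similarity matrix with entries in \[0, 1\].
#' @export
symptom_similarity <- function(disease_symptom) {
  X <- as.matrix(disease_symptom)
  if (any(X < 0)) stop("symptom matrix has negative entries")
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  Xn <- X / nrm
  S <- tcrossprod(Xn)
  S[zero, ] <- 0
  S[, zero] <- 0
  S[S > 1] <- 1
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(X), rownames(X))
  S
}

#' Fuse disease GAP similarity with symptom similarity
#'
#' Weighted sum `SD = SG + gamma * SS`. No renormalization is applied, so
#' fused entries may exceed 1; the downstream random walk row-normalizes.
#' If `SS` is `NULL` the GAP similarity is returned unchanged.
#'
#' @param SG disease GAP similarity matrix (m x m).
#' @param SS disease symptom similarity matrix (m x m) or `NULL`.
#' @param gamma nonnegative weight on the symptom similarity (default 0.9).
#' @return m x m fused disease similarity matrix.
#' @export
fuse_disease_similarity <- function(SG, SS = NULL, gamma = 0.9) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (is.null(SS)) return(SG)
  if (!all(dim(SG) == dim(SS))) stop("SG and SS dimensions differ")
  if (!is.null(rownames(SG)) && !is.null(rownames(SS)) &&
      !identical(rownames(SG), rownames(SS))) {
    stop("SG and SS label order differs")
  }
  SG + gamma * SS
}
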