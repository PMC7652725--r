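# Logistic matrix factorization with K-nearest-neighbor graph-Laplacian
# regularization. Microbes and diseases are embedded in a shared
# r-dimensional latent space; the association probability of pair (i, j) is
# sigma(a_i . b_j). Known positives count as c >= 1 observations each;
# selected reliable negatives count once; all other pairs are excluded from
# the likelihood (or included with weight 1 when no negative set is used).

#' K-nearest-neighbor graph Laplacian from a similarity matrix
#'
#' Keeps, per row, the K largest off-diagonal similarities (zero diagonal;
#' ties resolved toward the later entity, mirroring a stable descending
#' argsort), symmetrizes the resulting KNN affinity `W` as
#' `(W + t(W)) / 2`, and returns the combinatorial Laplacian `L = D - W`
#' with `D = diag(rowSums)`. `L` is symmetric positive semidefinite with
#' zero row sums.
#'
#' @param S k x k similarity matrix.
#' @param K neighborhood size, `1 <= K < k`.
#' @return k x k Laplacian matrix.
#' @export
build_laplacian <- function(S, K) {
  S <- as.matrix(S)
  k <- nrow(S)
  if (K < 1 || K >= k) stop("K must satisfy 1 <= K < nrow(S)")
  W <- matrix(0, k, k)
  for (i in seq_len(k)) {
    s <- S[i, ]
    s[i] <- -Inf
    nb <- order(s, seq_len(k), decreasing = TRUE)[seq_len(K)]
    W[i, nb] <- S[i, nb]
  }
  W <- (W + t(W)) / 2
  diag(W) <- 0
  diag(rowSums(W)) - W
}

# numerically safe log(1 + exp(x))
softplus <- function(x) {
  out <- x
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training-weight matrix for the weighted logistic likelihood
#'
#' Encodes which pairs enter the loss and with what multiplicity: known
#' positives get weight `c`, pairs in the supplied negative set get 1, and
#' everything else gets 0. With `negatives = NULL` all unlabeled pairs get
#' weight 1 instead (the no-negative-selection mode); pairs flagged in
#' `exclude` are always zeroed.
#'
#' @param Y n x m binary training matrix.
#' @param negatives a `negative_set`, or `NULL`.
#' @param c_weight positive-importance weight c >= 1.
#' @param exclude optional n x m logical matrix of pairs to drop from the
#'   loss (held-out test pairs).
#' @return n x m nonnegative weight matrix.
#' @export
build_training_weights <- function(Y, negatives = NULL, c_weight = 8,
                                   exclude = NULL) {
  if (c_weight < 1) stop("c_weight must be >= 1")
  Y <- as.matrix(Y)
  if (is.null(negatives)) {
    W <- matrix(1, nrow(Y), ncol(Y))
  } else {
    W <- matrix(0, nrow(Y), ncol(Y))
    if (nrow(negatives$pairs) > 0) W[negatives$pairs] <- 1
  }
  W[Y == 1] <- c_weight
  if (!is.null(exclude)) W[exclude & Y == 0] <- 0
  W
}

#' Regularized weighted logistic-loss objective
#'
#' Evaluates, over the active pairs (`W > 0`),
#' `sum (1 + c*y - y) * log(1 + exp(x)) - c*y*x` with `x = a_i . b_j`,
#' plus `tr(A' (lambda_m I + alpha L_m) A) / 2` and the matching disease
#' penalty. Lower is better; the fit minimizes this.
#'
#' @param A,B latent factor matrices (n x r, m x r).
#' @param Y binary training matrix.
#' @param W training weight matrix from [build_training_weights()].
#' @param L_m,L_d microbe/disease Laplacians (or `NULL` for alpha = 0).
#' @param c_weight,lambda_m,lambda_d,alpha model hyperparameters.
#' @return Scalar objective value.
#' @export
nrlmf_objective <- function(A, B, Y, W, L_m = NULL, L_d = NULL,
                            c_weight = 8, lambda_m = 0.125,
                            lambda_d = 0.125, alpha = 0.25) {
  X <- tcrossprod(A, B)
  M <- W > 0
  loss <- sum(((1 + c_weight * Y - Y) * softplus(X) - c_weight * Y * X)[M])
  Rm <- lambda_m * A
  Rd <- lambda_d * B
  if (alpha > 0 && !is.null(L_m)) Rm <- Rm + alpha * (L_m %*% A)
  if (alpha > 0 && !is.null(L_d)) Rd <- Rd + alpha * (L_d %*% B)
  loss + 0.5 * sum(A * Rm) + 0.5 * sum(B * Rd)
}

#' Analytic gradients of [nrlmf_objective()]
#'
#' @inheritParams nrlmf_objective
#' @return List with elements `A` and `B`, the gradients with respect to
#'   each factor matrix.
#' @export
nrlmf_gradients <- function(A, B, Y, W, L_m = NULL, L_d = NULL,
                            c_weight = 8, lambda_m = 0.125,
                            lambda_d = 0.125, alpha = 0.25) {
  X <- tcrossprod(A, B)
  M <- (W > 0) * 1
  G <- M * ((1 + c_weight * Y - Y) * sigmoid(X) - c_weight * Y)
  gA <- G %*% B + lambda_m * A
  gB <- crossprod(G, A) + lambda_d * B
  if (alpha > 0 && !is.null(L_m)) gA <- gA + alpha * (L_m %*% A)
  if (alpha > 0 && !is.null(L_d)) gB <- gB + alpha * (L_d %*% B)
  list(A = gA, B = gB)
}

#' Fit the neighborhood-regularized logistic matrix factorization
#'
#' Full-batch alternating AdaGrad-scaled gradient descent on the weighted
#' logistic loss: each iteration updates A with B fixed, then B with A
#' fixed, with per-entry learning rates `lr / sqrt(sum of squared past
#' gradients)`. Factors start from seeded Gaussian noise with standard
#' deviation `1 / sqrt(r)`. The iteration budget is fixed (no tolerance
#' stopping), so runtime is deterministic.
#'
#' @param Y n x m binary training matrix.
#' @param W training weight matrix (see [build_training_weights()]).
#' @param SM,SD similarity matrices used to build the KNN Laplacians; may
#'   be `NULL` when `alpha = 0`.
#' @param rank latent dimension r (default 20).
#' @param c_weight positive-importance weight (default 8).
#' @param lambda_m,lambda_d L2 penalties (default 0.125).
#' @param alpha Laplacian weight (default 0.25).
#' @param knn neighborhood size K (default 5).
#' @param learning_rate AdaGrad base step (default 0.1).
#' @param max_iter iteration budget (default 100).
#' @param seed RNG seed for the factor initialization.
#' @return Object of class `nrlmf_factors`: list with `A`, `B`, `objective`
#'   (trace of objective values, length `max_iter + 1`), plus the
#'   hyperparameters used.
#' @export
nrlmf_fit <- function(Y, W, SM = NULL, SD = NULL, rank = 20, c_weight = 8,
                      lambda_m = 0.125, lambda_d = 0.125, alpha = 0.25,
                      knn = 5, learning_rate = 0.1, max_iter = 100L,
                      seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); m <- ncol(Y)
  if (rank > min(n, m)) stop("rank must be <= min(n, m)")
  L_m <- L_d <- NULL
  if (alpha > 0) {
    if (is.null(SM) || is.null(SD)) stop("alpha > 0 requires SM and SD")
    L_m <- build_laplacian(SM, knn)
    L_d <- build_laplacian(SD, knn)
  }
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::rnorm(n * rank, sd = 1 / sqrt(rank)), n, rank)
  B <- matrix(stats::rnorm(m * rank, sd = 1 / sqrt(rank)), m, rank)
  accA <- matrix(0, n, rank)
  accB <- matrix(0, m, rank)
  eps <- 1e-8
  obj <- numeric(max_iter + 1L)
  obj[1L] <- nrlmf_objective(A, B, Y, W, L_m, L_d, c_weight,
                             lambda_m, lambda_d, alpha)
  for (it in seq_len(max_iter)) {
    gA <- nrlmf_gradients(A, B, Y, W, L_m, L_d, c_weight,
                          lambda_m, lambda_d, alpha)$A
    accA <- accA + gA^2
    A <- A - learning_rate * gA / sqrt(accA + eps)
    gB <- nrlmf_gradients(A, B, Y, W, L_m, L_d, c_weight,
                          lambda_m, lambda_d, alpha)$B
    accB <- accB + gB^2
    B <- B - learning_rate * gB / sqrt(accB + eps)
    obj[it + 1L] <- nrlmf_objective(A, B, Y, W, L_m, L_d, c_weight,
                                    lambda_m, lambda_d, alpha)
    if (!is.finite(obj[it + 1L])) {
      stop("optimization diverged (non-finite objective) at iteration ", it)
    }
  }
  structure(list(A = A, B = B, objective = obj, rank = rank,
                 c_weight = c_weight, lambda_m = lambda_m,
                 lambda_d = lambda_d, alpha = alpha, knn = knn,
                 learning_rate = learning_rate, max_iter = max_iter),
            class = "nrlmf_factors")
}

#' Neighbor-smooth latent vectors of cold entities
#'
#' Entities with no training positives (e.g. whole held-out microbes or
#' diseases under leave-rows/columns-out cross-validation) carry no
#' likelihood signal; their fitted vectors are essentially prior noise.
#' Each cold entity's latent vector is replaced by the similarity-weighted
#' average of its K most similar trained entities (weights = similarities,
#' normalized). Trained entities are left untouched.
#'
#' @param factors an `nrlmf_factors` object.
#' @param SM,SD microbe/disease similarity matrices.
#' @param trained_microbes,trained_diseases logical vectors marking
#'   entities with at least one training positive.
#' @param K neighborhood size (default: `factors$knn`).
#' @return The factors with cold rows of `A`/`B` replaced.
#' @export
neighbor_smooth_cold <- function(factors, SM, SD, trained_microbes,
                                 trained_diseases, K = factors$knn) {
  smooth <- function(F_mat, S, trained) {
    cold <- which(!trained)
    warm <- which(trained)
    if (length(cold) == 0L) return(F_mat)
    if (length(warm) == 0L) {
      warning("no trained neighbors available; cold entities keep fitted vectors")
      return(F_mat)
    }
    kk <- min(K, length(warm))
    for (i in cold) {
      s <- S[i, warm]
      nb <- order(s, decreasing = TRUE)[seq_len(kk)]
      w <- s[nb]
      if (sum(w) <= 0) {
        warning("cold entity has zero similarity to all trained entities; keeping fitted vector")
        next
      }
      F_mat[i, ] <- colSums(F_mat[warm[nb], , drop = FALSE] * (w / sum(w)))
    }
    F_mat
  }
  factors$A <- smooth(factors$A, SM, trained_microbes)
  factors$B <- smooth(factors$B, SD, trained_diseases)
  factors
}

#' Association probabilities from fitted factors
#'
#' `p_ij = sigma(a_i . b_j)`, computed overflow-safely. Because the sigmoid
#' is strictly increasing, rankings are identical to those of the raw
#' inner-product matrix `A B'`.
#'
#' @param factors an `nrlmf_factors` object (or any list with `A`, `B`).
#' @return n x m matrix of probabilities in (0, 1).
#' @export
predict_association <- function(factors) {
  sigmoid(tcrossprod(factors$A, factors$B))
}

#' @export
print.nrlmf_factors <- function(x, ...) {
  cat(sprintf("nrlmf_factors: %d x %d -> rank %d, final objective %.4f\n",
              nrow(x$A), nrow(x$B), x$rank,
              x$objective[length(x$objective)]))
  invisible(x)
}
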