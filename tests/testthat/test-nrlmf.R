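test_that("KNN Laplacian matches the hand-built 3-node chain and its contract", {
  S <- matrix(c(1, 1, 0,
                1, 1, 1,
                0, 1, 1), 3, 3)
  # hand construction: row 1 keeps its only neighbor 2; row 2 ties between
  # 1 and 3 and the stable-descending tie-break keeps 3; row 3 keeps 2.
  # (W + W')/2 gives edge weights {1-2: 0.5, 2-3: 1}; L = D - W.
  L <- build_laplacian(S, K = 1)
  expect_equal(L, rbind(c(0.5, -0.5, 0),
                        c(-0.5, 1.5, -1),
                        c(0, -1, 1)))
  expect_error(build_laplacian(S, K = 3), "K must")

  for (seed in 1:3) {
    Sr <- random_similarity(8, seed)
    Lr <- build_laplacian(Sr, K = 3)
    expect_equal(Lr, t(Lr))
    expect_lt(max(abs(rowSums(Lr))), 1e-12)
    set.seed(seed)
    for (i in 1:20) {
      x <- rnorm(8)
      expect_gte(drop(x %*% Lr %*% x), -1e-10)
    }
  }
})

test_that("objective has the closed-form value and slope at the origin", {
  Y <- rbind(c(1, 0), c(0, 1))
  W <- build_training_weights(Y, NULL, c_weight = 8)
  A0 <- matrix(0, 2, 2); B0 <- matrix(0, 2, 2)
  # at x = 0 a pair contributes (1 + (c-1) y) ln 2; with c = 1 that is
  # ln 2 for every active pair, with c = 8 positives weigh in at 8 ln 2
  W1 <- build_training_weights(Y, NULL, c_weight = 1)
  expect_equal(nrlmf_objective(A0, B0, Y, W1, c_weight = 1,
                               lambda_m = 0, lambda_d = 0, alpha = 0),
               4 * log(2))
  expect_equal(nrlmf_objective(A0, B0, Y, W, c_weight = 8,
                               lambda_m = 0, lambda_d = 0, alpha = 0),
               (2 * 8 + 2) * log(2))
  # single positive pair, c = 8: d/dx [c(ln(1+e^x) - x)] at 0 = c(sigma(0)-1) = -4
  g <- nrlmf_gradients(matrix(0, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1),
                       matrix(8, 1, 1), c_weight = 8,
                       lambda_m = 0, lambda_d = 0, alpha = 0)
  expect_equal(g$A[1, 1], -4)
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 6; m <- 4; r <- 2
    Y <- random_Y(n, m, p = 0.3, seed = seed)
    A <- matrix(rnorm(n * r), n, r)
    B <- matrix(rnorm(m * r), m, r)
    SM <- random_similarity(n, seed + 20)
    SD <- random_similarity(m, seed + 40)
    L_m <- build_laplacian(SM, 2); L_d <- build_laplacian(SD, 2)
    rn <- structure(list(pairs = which(Y == 0, arr.ind = TRUE)[1:3, ],
                         scores = rep(0, 3), am_min = 1, fallback = FALSE),
                    class = "negative_set")
    for (W in list(build_training_weights(Y, NULL, 8),
                   build_training_weights(Y, rn, 8))) {
      g <- nrlmf_gradients(A, B, Y, W, L_m, L_d, 8, 0.125, 0.125, 0.5)
      fA <- function(Ax) nrlmf_objective(Ax, B, Y, W, L_m, L_d, 8, 0.125, 0.125, 0.5)
      fB <- function(Bx) nrlmf_objective(A, Bx, Y, W, L_m, L_d, 8, 0.125, 0.125, 0.5)
      nA <- numeric_gradient(fA, A)
      nB <- numeric_gradient(fB, B)
      expect_lt(max(abs(g$A - nA) / pmax(abs(nA), 1)), 1e-5)
      expect_lt(max(abs(g$B - nB) / pmax(abs(nB), 1)), 1e-5)
    }
  }
})

test_that("training weights encode positives, negatives, exclusions", {
  Y <- rbind(c(1, 0, 0), c(0, 1, 0))
  rn <- structure(list(pairs = cbind(1L, 2L), scores = 0, am_min = 1,
                       fallback = FALSE), class = "negative_set")
  W <- build_training_weights(Y, rn, c_weight = 8)
  expect_equal(W[1, 1], 8)      # positive
  expect_equal(W[1, 2], 1)      # selected negative
  expect_equal(W[2, 3], 0)      # unselected unlabeled
  excl <- matrix(FALSE, 2, 3); excl[1, 3] <- TRUE
  W2 <- build_training_weights(Y, NULL, 8, exclude = excl)
  expect_equal(W2[1, 3], 0)     # excluded test pair
  expect_equal(W2[2, 3], 1)     # all-unlabeled mode elsewhere
  expect_error(build_training_weights(Y, NULL, 0.5), "c_weight")
})

test_that("fit descends, is seed-deterministic, and recovers noiseless low-rank structure", {
  Y <- matrix(c(1, 0, 0, 1, 1, 0, 0, 1, 1, 0, 0, 1), 6, 2)
  Y <- cbind(Y, 1 - Y)
  W <- build_training_weights(Y, NULL, 8)
  SM <- gap_similarity(Y); SD <- gap_similarity(t(Y))
  fit <- nrlmf_fit(Y, W, SM, SD, rank = 2, knn = 2, seed = 3)
  expect_true(all(diff(fit$objective) <= 1e-9))  # monotone on this instance
  expect_lt(fit$objective[length(fit$objective)], fit$objective[1])
  fit2 <- nrlmf_fit(Y, W, SM, SD, rank = 2, knn = 2, seed = 3)
  expect_identical(fit$A, fit2$A)

  # objective is rotation-invariant when alpha = 0 (latent gauge symmetry)
  set.seed(4)
  A <- matrix(rnorm(12), 6, 2); B <- matrix(rnorm(8), 4, 2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(nrlmf_objective(A, B, Y, W, c_weight = 8, lambda_m = 0.2,
                               lambda_d = 0.2, alpha = 0),
               nrlmf_objective(A %*% R, B %*% R, Y, W, c_weight = 8,
                               lambda_m = 0.2, lambda_d = 0.2, alpha = 0))

  # noiseless rank-2 pattern, c = 1, alpha = 0, tiny lambda: training AUC -> 1
  set.seed(8)
  U <- matrix(rnorm(40), 20, 2); V <- matrix(rnorm(16), 8, 2)
  Yr <- (tcrossprod(U, V) > 0) * 1
  Wr <- build_training_weights(Yr, NULL, 1)
  fr <- nrlmf_fit(Yr, Wr, rank = 2, c_weight = 1, lambda_m = 1e-4,
                  lambda_d = 1e-4, alpha = 0, max_iter = 2000, seed = 2)
  expect_equal(auc_score(as.vector(predict_association(fr)), as.vector(Yr)), 1)
})

test_that("stronger similarity pulls equal-profile microbes together under alpha > 0", {
  set.seed(5)
  Y <- rbind(c(1, 0, 1, 0), c(1, 0, 1, 0), matrix(rbinom(16, 1, 0.4), 4, 4))
  W <- build_training_weights(Y, NULL, 8)
  SD <- gap_similarity(t(Y))
  with_s12 <- function(s) {
    S <- gap_similarity(Y); S[1, 2] <- S[2, 1] <- s
    fit <- nrlmf_fit(Y, W, S, SD, rank = 2, knn = 2, alpha = 2,
                     max_iter = 500, seed = 11)
    sqrt(sum((fit$A[1, ] - fit$A[2, ])^2))
  }
  expect_lt(with_s12(0.95), with_s12(0.05))
})

test_that("cold entities receive similarity-weighted neighbor averages", {
  factors <- structure(list(A = rbind(c(9, 9), c(1, 0), c(3, 4)),
                            B = matrix(1, 2, 2), knn = 2),
                       class = "nrlmf_factors")
  SM <- matrix(1, 3, 3)
  SM[1, 2] <- SM[2, 1] <- 3 / 4   # weight ratio 3:1 after normalization
  SM[1, 3] <- SM[3, 1] <- 1 / 4
  sm <- neighbor_smooth_cold(factors, SM, matrix(1, 2, 2),
                             trained_microbes = c(FALSE, TRUE, TRUE),
                             trained_diseases = c(TRUE, TRUE), K = 2)
  expect_equal(sm$A[1, ], 0.75 * c(1, 0) + 0.25 * c(3, 4))
  expect_equal(sm$A[2, ], c(1, 0))     # trained rows untouched
  expect_equal(sm$B, factors$B)

  # identical neighbor vectors pass through unchanged; all-trained is identity
  factors2 <- factors
  factors2$A <- rbind(c(0, 0), c(5, 5), c(5, 5))
  sm2 <- neighbor_smooth_cold(factors2, SM, matrix(1, 2, 2),
                              c(FALSE, TRUE, TRUE), c(TRUE, TRUE), K = 2)
  expect_equal(sm2$A[1, ], c(5, 5))
  sm3 <- neighbor_smooth_cold(factors, SM, matrix(1, 2, 2),
                              c(TRUE, TRUE, TRUE), c(TRUE, TRUE), K = 2)
  expect_identical(sm3$A, factors$A)
})

test_that("predicted probabilities are a monotone transform of the inner products", {
  set.seed(6)
  f <- list(A = matrix(rnorm(10), 5, 2), B = matrix(rnorm(6), 3, 2))
  P <- predict_association(f)
  X <- tcrossprod(f$A, f$B)
  expect_true(all(P > 0 & P < 1))
  expect_equal(order(P), order(X))
  expect_equal(predict_association(list(A = matrix(0, 1, 1),
                                        B = matrix(0, 1, 1)))[1, 1], 0.5)
  # saturation without overflow
  expect_equal(predict_association(list(A = matrix(500, 1, 1),
                                        B = matrix(2, 1, 1)))[1, 1], 1)
})
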