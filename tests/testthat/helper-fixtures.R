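# Shared fixtures: tiny deterministic worlds built in code.

# minimal 3 x 2 dataset used across module tests
toy_dataset <- function() {
  Y <- matrix(c(1, 0,
                0, 1,
                1, 0), nrow = 3, byrow = TRUE)
  mda_dataset(c("mA", "mB", "mC"), c("dX", "dY"), Y)
}

# random binary matrix with at least one positive
random_Y <- function(n, m, p = 0.3, seed = 1) {
  set.seed(seed)
  Y <- matrix(rbinom(n * m, 1, p), n, m)
  if (sum(Y) == 0) Y[1, 1] <- 1
  Y
}

# random valid similarity matrix (symmetric, nonnegative, unit diagonal)
random_similarity <- function(k, seed = 1) {
  set.seed(seed)
  S <- matrix(runif(k * k), k, k)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

# direct linear-solve RWR oracle: theta * (I - (1-theta) H')^{-1} p0
rwr_oracle <- function(H, p0, theta) {
  nm <- nrow(H)
  drop(theta * solve(diag(nm) - (1 - theta) * t(H), p0))
}

# central finite differences of a scalar function, the gradient oracle
numeric_gradient <- function(f, M, h = 1e-6) {
  G <- M * 0
  for (i in seq_along(M)) {
    Mp <- M; Mm <- M
    Mp[i] <- M[i] + h
    Mm[i] <- M[i] - h
    G[i] <- (f(Mp) - f(Mm)) / (2 * h)
  }
  G
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
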