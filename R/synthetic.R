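# Synthetic microbe-disease worlds with planted low-rank logistic
# structure. The generative model matches the factorization's own
# assumption (p = sigma(U V' + b0)), so parameter-recovery tests are
# meaningful, and the symptom matrix is a nonnegative mixing of the
# disease factors so symptom similarity genuinely correlates with latent
# proximity.

#' Specification of a synthetic association world
#'
#' @param n,m microbe and disease counts.
#' @param r_true planted latent rank (`r_true = 0` gives an intercept-only,
#'   signal-free world).
#' @param density_target expected fraction of 1s in the sampled matrix,
#'   in (0, 1).
#' @param symptom_dims number of symptom columns q.
#' @param noise_flip probability that any entry of the sampled binary
#'   matrix is flipped, in \[0, 0.5).
#' @param seed RNG seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 292L, m = 39L, r_true = 4L,
                           density_target = 0.0395, symptom_dims = 50L,
                           noise_flip = 0.02, seed = 1L) {
  if (density_target <= 0 || density_target >= 1) {
    stop("density_target must be in (0, 1)")
  }
  if (noise_flip < 0 || noise_flip >= 0.5) stop("noise_flip must be in [0, 0.5)")
  if (r_true > min(n, m)) stop("r_true must be <= min(n, m)")
  if (n < 1 || m < 1 || symptom_dims < 1) stop("degenerate dimensions")
  structure(list(n = as.integer(n), m = as.integer(m),
                 r_true = as.integer(r_true),
                 density_target = density_target,
                 symptom_dims = as.integer(symptom_dims),
                 noise_flip = noise_flip, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Preset mimicking the scale of the curated human microbe-disease catalog
#'
#' 292 microbes x 39 diseases at ~3.95% density (450 expected positives),
#' planted rank 4, 50 symptom dimensions, 2% label noise.
#'
#' @param seed RNG seed (default 1).
#' @return A [synthetic_spec()].
#' @export
hmdad_like_preset <- function(seed = 1L) {
  synthetic_spec(n = 292L, m = 39L, r_true = 4L, density_target = 0.0395,
                 symptom_dims = 50L, noise_flip = 0.02, seed = seed)
}

# intercept b0 such that mean(sigmoid(X + b0)) hits the target density,
# solved by bisection (mean is strictly increasing in b0)
solve_intercept <- function(X, target, tol = 1e-3) {
  f <- function(b) mean(1 / (1 + exp(-(X + b)))) - target
  lo <- -30; hi <- 30
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) <= tol) return(mid)
    if (v > 0) hi <- mid else lo <- mid
  }
  mid
}

#' Generate a synthetic association world
#'
#' Draws planted factors `U` (n x r), `V` (m x r) i.i.d. standard normal,
#' solves the intercept `b0` by bisection so that the expected density of
#' the generated matrix — after label flips — matches `density_target`
#' within 1e-3 (i.e. `mean(p)` is targeted at
#' `(density_target - noise_flip) / (1 - 2 * noise_flip)`), samples
#' `Y ~ Bernoulli(p)`, applies independent label flips, and builds a
#' symptom matrix `softplus(V G)` from a random mixing matrix `G` (r x q).
#'
#' @param spec a [synthetic_spec()].
#' @return List with `dataset` (an [mda_dataset()]), `prob` (n x m true
#'   association probabilities), `symptom` (m x q matrix), `U`, `V`, `b0`.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n; m <- spec$m; r <- spec$r_true
  X <- if (r > 0) {
    U <- matrix(stats::rnorm(n * r), n, r)
    V <- matrix(stats::rnorm(m * r), m, r)
    tcrossprod(U, V)
  } else {
    U <- matrix(0, n, 0); V <- matrix(0, m, 0)
    matrix(0, n, m)
  }
  # flips move the expected density to d*(1-f) + (1-d)*f; invert so the
  # realized matrix, not the pre-noise p, hits the target
  pre_target <- (spec$density_target - spec$noise_flip) /
    (1 - 2 * spec$noise_flip)
  if (pre_target <= 0) {
    stop("noise_flip is too large for the requested density_target")
  }
  b0 <- solve_intercept(X, pre_target)
  p <- 1 / (1 + exp(-(X + b0)))
  Y <- matrix(stats::rbinom(n * m, 1L, p), n, m)
  if (spec$noise_flip > 0) {
    flip <- matrix(stats::runif(n * m) < spec$noise_flip, n, m)
    Y[flip] <- 1 - Y[flip]
  }
  if (sum(Y) == 0) Y[which.max(p)] <- 1  # guard: keep the dataset non-empty
  q <- spec$symptom_dims
  G <- matrix(stats::rnorm(max(r, 1) * q), max(r, 1), q)
  symptom <- if (r > 0) softplus(V %*% G)
             else matrix(softplus(stats::rnorm(m * q)), m, q)
  microbes <- sprintf("microbe_%03d", seq_len(n))
  diseases <- sprintf("disease_%02d", seq_len(m))
  rownames(symptom) <- diseases
  colnames(symptom) <- sprintf("symptom_%02d", seq_len(q))
  list(dataset = mda_dataset(microbes, diseases, Y),
       prob = p, symptom = symptom, U = U, V = V, b0 = b0)
}
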