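#' Build the heterogeneous-network transition matrix
#'
#' Stacks the microbe similarity network, the disease similarity network and
#' the bipartite association network into one (n + m)-node graph with state
#' order \[microbes; diseases\], and converts it to a row-stochastic
#' transition matrix. A walker on a microbe node with at least one known
#' association jumps to the disease side with total probability
#' `lambda_jump` (split across its diseases proportionally to `Y`) and stays
#' on the microbe side with probability `1 - lambda_jump` (split
#' proportionally to similarity); a microbe with no associations walks on
#' the similarity network only. Disease rows are handled symmetrically.
#'
#' @param SM n x n microbe similarity matrix with positive row sums.
#' @param SD m x m disease similarity matrix with positive row sums.
#' @param Y n x m binary association matrix.
#' @param lambda_jump jump probability in \[0, 1\] (default 0.9).
#' @return An object of class `hetero_transition`: list with blocks `H_MM`
#'   (n x n), `H_MD` (n x m), `H_DM` (m x n), `H_DD` (m x m), and
#'   `lambda_jump`.
#' @export
build_transition <- function(SM, SD, Y, lambda_jump = 0.9) {
  if (lambda_jump < 0 || lambda_jump > 1) stop("lambda_jump must be in [0, 1]")
  Y <- as.matrix(Y)
  n <- nrow(Y); m <- ncol(Y)
  if (!all(dim(SM) == c(n, n)) || !all(dim(SD) == c(m, m))) {
    stop("similarity matrix dimensions inconsistent with Y")
  }
  sm_rs <- rowSums(SM)
  sd_rs <- rowSums(SD)
  if (any(sm_rs <= 0) || any(sd_rs <= 0)) {
    stop("similarity row sums must be positive")
  }
  mic_deg <- rowSums(Y)
  dis_deg <- colSums(Y)

  H_MM <- SM / sm_rs
  H_MM[mic_deg > 0, ] <- (1 - lambda_jump) * H_MM[mic_deg > 0, , drop = FALSE]
  H_MD <- matrix(0, n, m)
  has <- mic_deg > 0
  H_MD[has, ] <- lambda_jump * Y[has, , drop = FALSE] / mic_deg[has]

  H_DD <- SD / sd_rs
  H_DD[dis_deg > 0, ] <- (1 - lambda_jump) * H_DD[dis_deg > 0, , drop = FALSE]
  H_DM <- matrix(0, m, n)
  hasd <- dis_deg > 0
  H_DM[hasd, ] <- lambda_jump * t(Y)[hasd, , drop = FALSE] / dis_deg[hasd]

  structure(list(H_MM = H_MM, H_MD = H_MD, H_DM = H_DM, H_DD = H_DD,
                 lambda_jump = lambda_jump, n = n, m = m),
            class = "hetero_transition")
}

#' Assemble the full (n + m) x (n + m) transition matrix
#'
#' @param trans a `hetero_transition`.
#' @return Row-stochastic matrix in \[microbes; diseases\] state order.
#' @export
transition_matrix <- function(trans) {
  rbind(cbind(trans$H_MM, trans$H_MD),
        cbind(trans$H_DM, trans$H_DD))
}

#' Restart distribution for a query entity
#'
#' For a disease query, the disease block carries mass `eta` on the query
#' node and the microbe block carries `1 - eta` spread uniformly over the
#' microbes known to associate with it (the seed microbes); with `eta <
#' 0.5` the walker restarts preferentially from seed microbes. A query with
#' no known partners gets full mass on its own node. For a microbe query
#' the roles are mirrored (mass `eta` on the query microbe, `1 - eta` on
#' its seed diseases).
#'
#' @param query index of the query entity on its own axis.
#' @param Y n x m binary training association matrix.
#' @param eta query-node restart weight in \[0, 1\] (default 0.9).
#' @param type `"disease"` (default) or `"microbe"`.
#' @return Restart probability vector of length n + m summing to 1.
#' @export
initial_distribution <- function(query, Y, eta = 0.9, type = c("disease", "microbe")) {
  type <- match.arg(type)
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  Y <- as.matrix(Y)
  n <- nrow(Y); m <- ncol(Y)
  p0 <- numeric(n + m)
  if (type == "disease") {
    if (query < 1 || query > m) stop("disease index out of bounds")
    seeds <- which(Y[, query] == 1)
    if (length(seeds) == 0L) {
      p0[n + query] <- 1
    } else {
      p0[n + query] <- eta
      p0[seeds] <- (1 - eta) / length(seeds)
    }
  } else {
    if (query < 1 || query > n) stop("microbe index out of bounds")
    seeds <- which(Y[query, ] == 1)
    if (length(seeds) == 0L) {
      p0[query] <- 1
    } else {
      p0[query] <- eta
      p0[n + seeds] <- (1 - eta) / length(seeds)
    }
  }
  p0
}

#' Random walk with restart on the heterogeneous network
#'
#' Power iteration `P(t+1) = (1 - theta) * t(H) %*% P(t) + theta * P(0)`
#' from `P(0) = p0` until the Frobenius norm of the update falls below
#' `tol`. `p0` may be a matrix whose columns are independent restart
#' vectors; all walks are iterated jointly.
#'
#' @param trans a `hetero_transition`.
#' @param p0 restart vector of length n + m (or matrix with such columns),
#'   each column summing to 1.
#' @param theta restart probability in (0, 1\] (default 0.5).
#' @param tol convergence tolerance on the Frobenius norm of the update
#'   (default 1e-11).
#' @param max_iter iteration cap (default 10000); reaching it raises a
#'   warning and returns the last iterate.
#' @return Stationary probability vector/matrix, same shape as `p0`.
#' @export
rwr_solve <- function(trans, p0, theta = 0.5, tol = 1e-11, max_iter = 10000L) {
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  if (tol <= 0) stop("tol must be > 0")
  H <- transition_matrix(trans)
  rs <- rowSums(H)
  if (max(abs(rs - 1)) > 1e-10) stop("transition matrix is not row-stochastic")
  was_vector <- is.null(dim(p0))
  p0 <- as.matrix(p0)
  if (nrow(p0) != nrow(H)) stop("p0 length does not match network size")
  if (max(abs(colSums(p0) - 1)) > 1e-8) stop("restart vectors must sum to 1")
  Ht <- t(H)
  P <- p0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P_new <- (1 - theta) * (Ht %*% P) + theta * p0
    if (sqrt(sum((P_new - P)^2)) <= tol) {
      P <- P_new
      converged <- TRUE
      break
    }
    P <- P_new
  }
  if (!converged) warning("RWR did not converge within max_iter; returning last iterate")
  if (was_vector) drop(P) else P
}

#' Score all microbe-disease pairs by random walk with restart
#'
#' Disease-centric mode runs one restart per disease and reads out the
#' microbe block of the stationary distribution; microbe-centric mode is
#' the mirror image (per-microbe restarts, disease-block read-out);
#' `"average"` averages the two score matrices.
#'
#' @param SM,SD,Y_train network inputs as in [build_transition()].
#' @param lambda_jump jump probability (default 0.9).
#' @param theta restart probability (default 0.5).
#' @param eta query-node restart weight (default 0.9).
#' @param tol,max_iter convergence controls passed to [rwr_solve()].
#' @param mode `"disease"`, `"microbe"`, or `"average"`.
#' @return n x m score matrix `AM`.
#' @export
score_all_pairs <- function(SM, SD, Y_train, lambda_jump = 0.9, theta = 0.5,
                            eta = 0.9, tol = 1e-11, max_iter = 10000L,
                            mode = c("disease", "microbe", "average")) {
  mode <- match.arg(mode)
  Y_train <- as.matrix(Y_train)
  n <- nrow(Y_train); m <- ncol(Y_train)
  trans <- build_transition(SM, SD, Y_train, lambda_jump)
  score_one_side <- function(type) {
    k <- if (type == "disease") m else n
    P0 <- vapply(seq_len(k),
                 function(q) initial_distribution(q, Y_train, eta, type),
                 numeric(n + m))
    Pstar <- rwr_solve(trans, P0, theta = theta, tol = tol, max_iter = max_iter)
    Pstar <- as.matrix(Pstar)
    if (type == "disease") {
      Pstar[seq_len(n), , drop = FALSE]          # microbe block, one col per disease
    } else {
      t(Pstar[n + seq_len(m), , drop = FALSE])   # disease block, one row per microbe
    }
  }
  AM <- switch(mode,
    disease = score_one_side("disease"),
    microbe = score_one_side("microbe"),
    average = (score_one_side("disease") + score_one_side("microbe")) / 2)
  dimnames(AM) <- dimnames(Y_train)
  AM
}
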