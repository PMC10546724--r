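# Sparse inverse covariance estimation with an elementwise penalty matrix
# (blockwise coordinate descent, Friedman-style). Used by the
# co-accessibility stage with a genomic-distance-dependent penalty.

# lasso sub-problem: minimize (1/2) b' W11 b - s12' b + sum(rho12 |b|)
# by cyclic coordinate descent with soft-thresholding.
lasso_cd <- function(W11, s12, rho12, beta0 = NULL, tol = 1e-6,
                     maxit = 500L) {
  p <- length(s12)
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      r <- s12[j] - drop(W11[j, -j, drop = FALSE] %*% beta[-j])
      new <- sign(r) * max(abs(r) - rho12[j], 0) / W11[j, j]
      delta <- max(delta, abs(new - beta[j]))
      beta[j] <- new
    }
    if (delta < tol) break
  }
  beta
}

#' Graphical lasso with an elementwise penalty matrix
#'
#' Estimates a sparse precision matrix from an empirical covariance under
#' an L1 penalty that may differ per matrix entry, by blockwise coordinate
#' descent on the covariance estimate. A non-positive-definite input is
#' ridge-shrunk (`eps` added to the diagonal, logged via a message).
#'
#' @param S Empirical covariance (p x p, symmetric).
#' @param rho Penalty: scalar or p x p symmetric matrix of non-negative
#'   entries (use very large entries to force structural zeros).
#' @param tol Convergence tolerance on the covariance estimate.
#' @param maxit Maximum outer sweeps.
#' @param eps Ridge added when `S` is not positive definite.
#' @return List with `precision`, `covariance`, `partial_cor` (off-diagonal
#'   partial correlations, unit diagonal), `iterations`.
#' @export
glasso_penalized <- function(S, rho, tol = 1e-5, maxit = 100L, eps = 1e-3) {
  p <- ncol(S)
  stopifnot(nrow(S) == p)
  if (length(rho) == 1L) rho <- matrix(rho, p, p)
  stopifnot(all(dim(rho) == c(p, p)), all(rho >= 0))
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    message("covariance not positive definite; ridge ", eps, " applied")
    S <- S + diag(eps, p)
  }
  if (p == 1L)
    return(list(precision = matrix(1 / S[1, 1]), covariance = S,
                partial_cor = matrix(1), iterations = 0L))
  W <- S + diag(diag(rho))
  B <- matrix(0, p, p)  # per-column lasso coefficients, warm-started
  it <- 0L
  repeat {
    it <- it + 1L
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      beta <- lasso_cd(W[idx, idx, drop = FALSE], S[idx, j], rho[idx, j],
                       beta0 = B[idx, j])
      B[idx, j] <- beta
      W[idx, j] <- W[j, idx] <- drop(W[idx, idx, drop = FALSE] %*% beta)
    }
    if (max(abs(W - W_old)) < tol * mean(abs(diag(S))) || it >= maxit) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    denom <- W[j, j] - drop(W[idx, j] %*% B[idx, j])
    Theta[j, j] <- 1 / denom
    Theta[idx, j] <- -B[idx, j] * Theta[j, j]
  }
  Theta <- (Theta + t(Theta)) / 2
  d <- sqrt(diag(Theta))
  pc <- -Theta / tcrossprod(d)
  diag(pc) <- 1
  list(precision = Theta, covariance = W, partial_cor = pc,
       iterations = it)
}
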