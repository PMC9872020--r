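## Minimal symmetric fastICA (logcosh contrast) used for ocular-artifact
## removal.  Whitening is by eigendecomposition of the channel covariance;
## the unmixing search uses symmetric decorrelation, which makes the result
## independent of component ordering.

fast_ica <- function(X, n_components = NULL, tol = 1e-4, max_iter = 200L,
                     seed = 1L) {
  # X: channels x samples, assumed roughly zero-mean per channel
  X <- sweep(X, 1, rowMeans(X))
  d <- nrow(X); n <- ncol(X)
  if (is.null(n_components)) n_components <- d
  eg <- eigen(tcrossprod(X) / (n - 1), symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-10)
  n_components <- min(n_components, length(keep))
  if (n_components < 1) stop("data rank insufficient for ICA")
  K <- t(eg$vectors[, keep[seq_len(n_components)], drop = FALSE]) /
    sqrt(eg$values[keep[seq_len(n_components)]])     # whitening: Z = K X
  Z <- K %*% X
  W <- with_seed(seed, matrix(rnorm(n_components^2), n_components))
  sym_decorrelate <- function(W) {
    sw <- eigen(W %*% t(W), symmetric = TRUE)
    solve_sqrt <- sw$vectors %*% diag(1 / sqrt(pmax(sw$values, 1e-12)),
                                      n_components) %*% t(sw$vectors)
    solve_sqrt %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / n - diag(gprime, n_components) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  # sources S = W Z = (W K) X; mixing (channel space) M = pinv(W K)
  unmix <- W %*% K
  pinv <- function(M) {
    sv <- svd(M)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  }
  list(S = unmix %*% X, unmixing = unmix, mixing = pinv(unmix),
       converged = converged, iterations = it, n_components = n_components)
}
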