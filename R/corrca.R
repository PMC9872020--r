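## Correlated component analysis (CorrCA) and intersubject correlation.
##
## CorrCA finds channel-weight vectors w maximizing the ratio of
## between-subject to within-subject covariance,
##
##     rho(w) = (w' Rb w) / (w' Rw w),
##
## the multi-subject analogue of canonical correlation.  With per-subject
## centered data X_k (channels x samples) over the unmasked samples,
##
##     R_kl = X_k X_l' / (n - 1),
##     Rw   = mean_k R_kk,
##     Rb   = mean_{k != l} R_kl.
##
## The maximizers solve the generalized eigenproblem Rb w = rho Rw w; Rw is
## shrunk toward a scaled identity before inversion because zeroed bad
## channels make it rank-deficient.

#' Pooled within- and between-subject covariance of a recording
#'
#' @param rec A [multi_subject_recording()].
#' @param excised Optional logical mask (`TRUE` = excluded samples).
#' @return A `cov_pair`: list with symmetric `Rw`, `Rb`, `n_subjects`,
#'   `n_samples`.
#' @export
compute_covariances <- function(rec, excised = NULL) {
  stopifnot(inherits(rec, "multi_subject_recording"))
  N <- n_subjects(rec)
  if (N < 2) stop("covariances need at least 2 subjects")
  keep <- if (is.null(excised)) rep(TRUE, n_rec_samples(rec)) else !excised
  n <- sum(keep)
  if (n < 2) stop("need at least 2 unmasked samples")
  Xs <- lapply(rec$data, function(m) {
    m <- m[, keep, drop = FALSE]
    m - rowMeans(m)
  })
  D <- n_channels(rec)
  Rw <- matrix(0, D, D); Rb <- matrix(0, D, D)
  for (k in seq_len(N)) Rw <- Rw + tcrossprod(Xs[[k]]) / (n - 1)
  Xsum <- Reduce(`+`, Xs)
  Rall <- tcrossprod(Xsum) / (n - 1)           # sum over all k,l pairs
  Rb <- (Rall - Rw) / (N * (N - 1))            # off-diagonal pairs only
  Rw <- Rw / N
  Rw <- (Rw + t(Rw)) / 2; Rb <- (Rb + t(Rb)) / 2
  structure(list(Rw = Rw, Rb = Rb, n_subjects = N, n_samples = n),
            class = "cov_pair")
}

#' Average covariance pairs across stimuli
#'
#' Element-wise mean with equal weight per stimulus, so one set of
#' projection vectors serves all stimuli.
#'
#' @param pairs List of `cov_pair` objects with identical dimensions.
#' @return A `cov_pair`.
#' @export
average_covariances <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  D <- nrow(pairs[[1]]$Rw)
  if (!all(vapply(pairs, function(p) nrow(p$Rw) == D, logical(1))))
    stop("covariance pairs have mixed channel dimensions")
  structure(list(
    Rw = Reduce(`+`, lapply(pairs, `[[`, "Rw")) / length(pairs),
    Rb = Reduce(`+`, lapply(pairs, `[[`, "Rb")) / length(pairs),
    n_subjects = pairs[[1]]$n_subjects,
    n_samples = sum(vapply(pairs, `[[`, numeric(1), "n_samples"))),
    class = "cov_pair")
}

#' Fit correlated components
#'
#' Solves the generalized eigenproblem of `Rb` against the shrinkage-
#' regularized `Rw`,
#' `(1 - gamma) Rw + gamma (tr(Rw)/D) I`, orders components by descending
#' correlation `rho`, and computes the forward model
#' `A = Rw W (W' Rw W)^-1` for topographic interpretation.  Column signs
#' follow a fixed convention (largest-magnitude entry of each forward-model
#' column is positive) so results do not depend on subject ordering or
#' numerical libraries.
#'
#' @param cov A `cov_pair` from [compute_covariances()] /
#'   [average_covariances()].
#' @param gamma Shrinkage weight in `[0, 1]` (default 0.1).
#' @param n_components Number of components to keep (default: all).
#' @return A `spatial_filters`: list with `W`, `A`, `rho`, `gamma`.
#' @export
fit_corrca <- function(cov, gamma = 0.1, n_components = NULL) {
  stopifnot(inherits(cov, "cov_pair"), gamma >= 0, gamma <= 1)
  D <- nrow(cov$Rw)
  Rw_reg <- (1 - gamma) * cov$Rw + gamma * (sum(diag(cov$Rw)) / D) * diag(D)
  L <- tryCatch(chol(Rw_reg), error = function(e)
    stop("regularized within-subject covariance is not invertible; ",
         "raise gamma"))
  # whiten: M = L'^-1 Rb L^-1, symmetric eigenproblem
  Li <- backsolve(L, diag(D))
  M <- t(Li) %*% cov$Rb %*% Li
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- Li %*% eg$vectors
  rho <- eg$values
  if (is.null(n_components)) n_components <- D
  n_components <- min(n_components, D)
  W <- W[, seq_len(n_components), drop = FALSE]
  rho <- rho[seq_len(n_components)]
  # forward model from the regularized covariance: with zeroed channels the
  # raw Rw is singular and W'RwW would not be invertible
  G <- t(W) %*% Rw_reg %*% W
  A <- Rw_reg %*% W %*% solve(G)
  sgn <- vapply(seq_len(ncol(A)), function(j) {
    v <- A[, j]; s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  }, numeric(1))
  A <- sweep(A, 2, sgn, `*`)
  W <- sweep(W, 2, sgn, `*`)
  structure(list(W = W, A = A, rho = rho, gamma = gamma),
            class = "spatial_filters")
}

#' @export
print.spatial_filters <- function(x, ...) {
  cat(sprintf("spatial_filters: %d components (gamma = %g)\n  rho: %s\n",
              ncol(x$W), x$gamma,
              paste(sprintf("%.3f", head(x$rho, 5)), collapse = ", ")))
  invisible(x)
}

## Project every subject onto the first K components.
## Returns list over components of samples x subjects matrices.
project_components <- function(rec, filters, K) {
  if (K > ncol(filters$W))
    stop("K exceeds available components")
  lapply(seq_len(K), function(c_i) {
    w <- filters$W[, c_i]
    vapply(rec$data, function(X) as.numeric(w %*% X),
           numeric(n_rec_samples(rec)))
  })
}

## Leave-one-out correlations for one component: cor of each subject's
## series with the mean of all the others.  Y is samples x subjects,
## already restricted to the samples in play.
loo_cor <- function(Y) {
  N <- ncol(Y)
  tot <- rowSums(Y)
  vapply(seq_len(N), function(k) {
    others <- (tot - Y[, k]) / (N - 1)
    if (sd(Y[, k]) < 1e-14 || sd(others) < 1e-14) 0 else cor(Y[, k], others)
  }, numeric(1))
}

#' Leave-one-out subject-level ISC
#'
#' For each subject and component: the Pearson correlation between that
#' subject's projected time course and the mean projected time course of
#' all other subjects.  A subject's ISC is the sum over the top `K`
#' components -- one number per participant summarizing how synchronized
#' their response is with the rest of the group.  A zero-variance
#' projection contributes 0.
#'
#' @param rec A (preprocessed) [multi_subject_recording()].
#' @param filters A `spatial_filters` from [fit_corrca()].
#' @param K Components summed (default 3).
#' @param excised Optional excision mask.
#' @return Named per-subject numeric vector.
#' @export
loo_isc <- function(rec, filters, K = 3L, excised = NULL) {
  stopifnot(inherits(rec, "multi_subject_recording"),
            inherits(filters, "spatial_filters"))
  keep <- if (is.null(excised)) rep(TRUE, n_rec_samples(rec)) else !excised
  proj <- project_components(rec, filters, K)
  acc <- numeric(n_subjects(rec))
  for (c_i in seq_len(K))
    acc <- acc + loo_cor(proj[[c_i]][keep, , drop = FALSE])
  setNames(acc, rec$subjects)
}

#' Time-resolved ISC on sliding windows
#'
#' Divides the recording into `window_len`-second windows every `hop`
#' seconds (default 1.5 s windows, 0.3 s hop: 1.2 s overlap) and computes
#' the leave-one-out per-subject ISC within each window, always projecting
#' with the globally fitted `W` (components are never refit per window);
#' per-subject means are re-removed within each window.  Windows whose
#' excised fraction exceeds `max_excised_frac` are dropped and flagged in
#' the grid.
#'
#' @param rec A (preprocessed) [multi_subject_recording()].
#' @param filters Global `spatial_filters`.
#' @param window_len Window length in seconds.
#' @param hop Hop in seconds (`window_len - overlap`).
#' @param K Components summed.
#' @param excised Optional excision mask.
#' @param max_excised_frac Drop windows with more than this excised
#'   fraction (default 0.5).
#' @return An `isc_series`: list with `global` (per-subject scalar ISC),
#'   `windows` (subjects x retained-windows matrix), `grid` (the shared
#'   window grid with `retained` flags), `window_len`, `hop`, `K`.
#' @export
time_resolved_isc <- function(rec, filters, window_len = 1.5, hop = 0.3,
                              K = 3L, excised = NULL,
                              max_excised_frac = 0.5) {
  stopifnot(inherits(rec, "multi_subject_recording"))
  grid <- window_grid(rec_duration(rec), window_len, hop)
  n <- n_rec_samples(rec)
  keep <- if (is.null(excised)) rep(TRUE, n) else !excised
  proj <- project_components(rec, filters, K)
  vals <- matrix(NA_real_, n_subjects(rec), nrow(grid),
                 dimnames = list(rec$subjects, NULL))
  for (w in seq_len(nrow(grid))) {
    idx <- window_sample_idx(grid$start[w], window_len, rec$fs, n)
    kept <- idx[keep[idx]]
    if (length(kept) < 2 ||
        (length(idx) - length(kept)) / length(idx) > max_excised_frac) {
      grid$retained[w] <- FALSE
      next
    }
    acc <- numeric(n_subjects(rec))
    for (c_i in seq_len(K)) {
      Y <- proj[[c_i]][kept, , drop = FALSE]
      Y <- sweep(Y, 2, colMeans(Y))
      acc <- acc + loo_cor(Y)
    }
    vals[, w] <- acc
  }
  structure(list(global = loo_isc(rec, filters, K, excised),
                 windows = vals[, grid$retained, drop = FALSE],
                 grid = grid, window_len = window_len, hop = hop,
                 K = as.integer(K)),
            class = "isc_series")
}

#' @export
print.isc_series <- function(x, ...) {
  cat(sprintf(
    "isc_series: %d subjects, %d/%d windows retained (%.1f s windows, %.1f s hop, K = %d)\n  mean global ISC: %.4f\n",
    nrow(x$windows), sum(x$grid$retained), nrow(x$grid), x$window_len,
    x$hop, x$K, mean(x$global)))
  invisible(x)
}
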