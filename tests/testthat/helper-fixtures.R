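# Small fixtures shared across tests.  Everything is built in code; sizes
# are deliberately tiny so the whole suite stays fast.

# A small synthetic configuration: 6 subjects, 1 block of two 15 s clips.
small_cfg <- function(seed = 1L, ...) {
  synth_config(n_subjects = 6L, n_channels = 16L, fs = 125,
               n_blocks = 1L, clip_lengths = c(15, 15), seed = seed, ...)
}

# Recording with identical subjects: n_ch independent band-limited signals.
identical_rec <- function(n_subjects = 5L, n_channels = 4L, n = 2000L,
                          fs = 250, seed = 7L) {
  X <- iscpipe:::with_seed(seed,
    matrix(rnorm(n_channels * n), n_channels, n))
  multi_subject_recording(rep(list(X), n_subjects), fs)
}

# Recording of independent white-noise subjects.
noise_rec <- function(n_subjects = 6L, n_channels = 8L, n = 1500L,
                      fs = 250, seed = 11L) {
  data <- iscpipe:::with_seed(seed, lapply(seq_len(n_subjects), function(k)
    matrix(rnorm(n_channels * n), n_channels, n)))
  multi_subject_recording(data, fs)
}

# Hand-made spatial filters projecting raw channels (identity-ish).
identity_filters <- function(n_channels, K = n_channels) {
  W <- diag(n_channels)[, seq_len(K), drop = FALSE]
  structure(list(W = W, A = W, rho = rep(1, K), gamma = 0),
            class = "spatial_filters")
}

# Brute-force CorrCA oracle for 2-channel covariances: ratio maximization
# over unit vectors on the half circle.
brute_corrca_2ch <- function(Rw, Rb, n_grid = 1e6) {
  th <- pi * (seq_len(n_grid) - 0.5) / n_grid
  c2 <- cos(th)^2; s2 <- sin(th)^2; cs <- cos(th) * sin(th)
  num <- Rb[1, 1] * c2 + 2 * Rb[1, 2] * cs + Rb[2, 2] * s2
  den <- Rw[1, 1] * c2 + 2 * Rw[1, 2] * cs + Rw[2, 2] * s2
  i <- which.max(num / den)
  list(rho = (num / den)[i], w = c(cos(th[i]), sin(th[i])))
}

# Random 2-channel covariance pair from actual multi-subject data, so Rw
# is well conditioned and Rb is a genuine between-subject covariance.
random_cov_2ch <- function(seed, n_subjects = 3L, n = 400L) {
  iscpipe:::with_seed(seed, {
    shared <- rbind(rnorm(n), rnorm(n))
    mix <- matrix(runif(4, -1, 1), 2, 2)
    data <- lapply(seq_len(n_subjects), function(k)
      mix %*% shared + matrix(rnorm(2 * n), 2, n))
    compute_covariances(multi_subject_recording(data, fs = 100))
  })
}

# Keypoint fixture with cleanly separated jitter / movement / cut scales.
keypoint_fixture <- function(seed = 5L) {
  cfg <- synth_config(n_subjects = 2L, n_channels = 4L, fs = 50,
                      n_blocks = 1L, clip_lengths = c(10, 10), fps = 25,
                      seed = seed)
  generate_keypoints(cfg, jitter_sd = 0.1, move_amp = 6, cut_jump = 100)
}

expect_file_equal <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}
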