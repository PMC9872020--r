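test_that("covariances match hand-computed values on a 3-sample toy", {
  # two subjects, two channels, three samples: brute-force arithmetic
  X1 <- rbind(c(1, 2, 3), c(0, 1, -1))
  X2 <- rbind(c(2, 0, 1), c(1, 1, 4))
  rec <- multi_subject_recording(list(a = X1, b = X2), fs = 10)
  cp <- compute_covariances(rec)
  c1 <- X1 - rowMeans(X1); c2 <- X2 - rowMeans(X2)
  R11 <- c1 %*% t(c1) / 2; R22 <- c2 %*% t(c2) / 2
  R12 <- c1 %*% t(c2) / 2; R21 <- c2 %*% t(c1) / 2
  expect_equal(cp$Rw, (R11 + R22) / 2)
  expect_equal(cp$Rb, (R12 + R21) / 2)
  expect_error(compute_covariances(
    multi_subject_recording(list(a = X1), fs = 10)), "2 subjects")
})

test_that("identical subjects give Rb = Rw and rho_1 = 1", {
  rec <- identical_rec()
  cp <- compute_covariances(rec)
  expect_equal(cp$Rb, cp$Rw, tolerance = 1e-12)
  flt <- fit_corrca(cp, gamma = 0)
  expect_equal(flt$rho[1], 1, tolerance = 1e-8)
  expect_equal(flt$rho[length(flt$rho)], 1, tolerance = 1e-8)
})

test_that("independent noise subjects give small between-subject covariance", {
  rec <- noise_rec(n_subjects = 6L, n_channels = 4L, n = 10000L, seed = 3L)
  cp <- compute_covariances(rec)
  expect_lt(norm(cp$Rb, "F") / norm(cp$Rw, "F"), 0.1)
})

test_that("average_covariances is an equally weighted element-wise mean", {
  p1 <- random_cov_2ch(1)
  expect_equal(average_covariances(list(p1))$Rw, p1$Rw)
  expect_equal(average_covariances(list(p1, p1))$Rb, p1$Rb)
  p2 <- p1; p2$Rw <- -p1$Rw; p2$Rb <- -p1$Rb
  avg <- average_covariances(list(p1, p2))
  expect_equal(avg$Rw, matrix(0, 2, 2))
  p3 <- compute_covariances(noise_rec(n_channels = 3L, n = 300L))
  expect_error(average_covariances(list(p1, p3)), "mixed")
})

test_that("fit_corrca matches brute-force ratio maximization on 2-channel toys", {
  for (seed in 1:4) {
    cp <- random_cov_2ch(seed)
    flt <- fit_corrca(cp, gamma = 0)
    oracle <- brute_corrca_2ch(cp$Rw, cp$Rb, n_grid = 2e5)
    expect_equal(flt$rho[1], oracle$rho, tolerance = 1e-3)
    w <- flt$W[, 1] / sqrt(sum(flt$W[, 1]^2))
    expect_gt(abs(sum(w * oracle$w)), 1 - 1e-3)
  }
})

test_that("fit_corrca recovers the generating mixing topography", {
  cfg <- small_cfg(seed = 23L)
  sim <- generate_eeg(cfg)
  flt <- fit_corrca(compute_covariances(sim$recording), gamma = 0.1)
  expect_gt(abs(cor(flt$A[, 1], cfg$mixing)), 0.95)
  expect_true(all(diff(flt$rho) <= 1e-12))   # descending
})

test_that("singular covariance is rejected with advice, shrinkage fixes it", {
  rec <- identical_rec(n_subjects = 3L, n_channels = 4L, n = 500L)
  rec$data <- lapply(rec$data, function(X) { X[4, ] <- 0; X })  # dead channel
  cp <- compute_covariances(rec)
  expect_error(fit_corrca(cp, gamma = 0), "raise gamma")
  flt <- fit_corrca(cp, gamma = 0.1)
  expect_equal(ncol(flt$W), 4)
})

test_that("loo ISC: identical subjects give K, anticorrelated subject gives -1", {
  rec <- identical_rec(n_subjects = 5L, n_channels = 4L)
  flt <- fit_corrca(compute_covariances(rec), gamma = 0)
  isc <- loo_isc(rec, flt, K = 3)
  expect_equal(unname(isc), rep(3, 5), tolerance = 1e-8)
  # subject 3 = -(mean of 1, 2) on channel 1, K = 1 with identity filters
  y <- iscpipe:::with_seed(31L, rnorm(300))
  z <- iscpipe:::with_seed(32L, rnorm(300))
  rec2 <- multi_subject_recording(list(
    s1 = rbind(y, rnorm(300)), s2 = rbind(z, rnorm(300)),
    s3 = rbind(-(y + z) / 2, rnorm(300))), fs = 100)
  isc2 <- loo_isc(rec2, identity_filters(2, 1), K = 1)
  expect_equal(unname(isc2["s3"]), -1, tolerance = 1e-10)
})

test_that("zero-variance projections contribute zero", {
  rec <- identical_rec(n_subjects = 3L, n_channels = 3L)
  rec$data <- lapply(rec$data, function(X) { X[2, ] <- 0; X })
  isc <- loo_isc(rec, identity_filters(3), K = 3)
  expect_equal(unname(isc), rep(2, 3), tolerance = 1e-8)  # comp 2 gives 0
})

test_that("windowed ISC has the right geometry", {
  # fs = 500: a 1.5 s window spans 750 samples
  expect_identical(samples_per_window(500, 1.5), 750L)
  # 10 s recording, 1.5 s windows, 0.3 s hop: 29 windows
  g <- window_grid(10, 1.5, 0.3)
  expect_equal(nrow(g), 29)
  # oracle: enumerate starts directly
  starts <- seq(0, by = 0.3, length.out = 1000)
  expect_equal(nrow(g), sum(starts + 1.5 <= 10 + 1e-9))
  expect_error(window_grid(10, 1.5, 1.5), "exceed hop")
  expect_error(window_grid(1, 1.5, 0.3), "longer than recording")
})

test_that("stationary identical subjects give ISC = K in every window", {
  rec <- identical_rec(n_subjects = 4L, n_channels = 4L, n = 2500L, fs = 250)
  flt <- fit_corrca(compute_covariances(rec), gamma = 0)
  ts <- time_resolved_isc(rec, flt, window_len = 1.5, hop = 0.3, K = 3)
  expect_equal(nrow(ts$grid), floor((10 - 1.5) / 0.3) + 1)
  expect_true(all(abs(ts$windows - 3) < 1e-8))
})

test_that("windows overlapping excision beyond the limit are dropped", {
  rec <- identical_rec(n_subjects = 3L, n_channels = 3L, n = 2500L, fs = 250)
  excised <- rep(FALSE, 2500)
  excised[1:625] <- TRUE   # first 2.5 s gone
  flt <- identity_filters(3)
  ts <- time_resolved_isc(rec, flt, excised = excised)
  # windows fully inside the excised span are dropped; late ones retained
  expect_false(any(ts$grid$retained[ts$grid$end <= 2.5]))
  expect_true(all(ts$grid$retained[ts$grid$start >= 2.5]))
  # boundary windows: dropped iff excised fraction > 0.5
  bnd <- which(ts$grid$start < 2.5 & ts$grid$end > 2.5)
  frac <- (2.5 - ts$grid$start[bnd]) / 1.5
  expect_identical(ts$grid$retained[bnd], frac <= 0.5)
})

test_that("ISC is invariant to common scaling and to subject order", {
  cfg <- small_cfg(seed = 29L)
  sim <- generate_eeg(cfg)
  rec <- sim$recording
  flt <- fit_corrca(compute_covariances(rec), gamma = 0.1)
  isc <- loo_isc(rec, flt, K = 3)
  ts <- time_resolved_isc(rec, flt, K = 3)
  # common positive scaling
  rec2 <- rec; rec2$data <- lapply(rec$data, function(X) 3.7 * X)
  flt2 <- fit_corrca(compute_covariances(rec2), gamma = 0.1)
  expect_equal(flt2$rho, flt$rho, tolerance = 1e-10)
  expect_equal(loo_isc(rec2, flt2, K = 3), isc, tolerance = 1e-10)
  expect_equal(time_resolved_isc(rec2, flt2, K = 3)$windows, ts$windows,
               tolerance = 1e-10)
  # subject order: sign convention keeps filters stable
  perm <- c(4, 2, 6, 1, 3, 5)
  rec3 <- rec; rec3$data <- rec$data[perm]; rec3$subjects <- rec$subjects[perm]
  flt3 <- fit_corrca(compute_covariances(rec3), gamma = 0.1)
  expect_equal(flt3$W[, 1], flt$W[, 1], tolerance = 1e-6)
  expect_equal(loo_isc(rec3, flt3, K = 3)[rec$subjects], isc,
               tolerance = 1e-8)
})

test_that("global mean ISC rises with the shared-signal gain", {
  gains <- c(0, 0.5, 1, 2)
  reps <- 5
  means <- matrix(NA_real_, reps, length(gains))
  for (gi in seq_along(gains)) for (r in seq_len(reps)) {
    cfg <- synth_config(n_subjects = 4L, n_channels = 8L, fs = 125,
                        n_blocks = 1L, clip_lengths = 30,
                        base_gain = gains[gi],
                        movement_gains = c(arm = 0, leg = 0, both = 0),
                        seed = 100L + 10L * gi + r)
    sim <- generate_eeg(cfg)
    flt <- fit_corrca(compute_covariances(sim$recording), gamma = 0.1)
    means[r, gi] <- mean(loo_isc(sim$recording, flt, K = 3))
  }
  expect_true(all(diff(colMeans(means)) > 0))
  ct <- suppressWarnings(stats::cor.test(
    rep(gains, each = reps), as.numeric(means), method = "spearman"))
  expect_lt(ct$p.value, 0.01)
})

test_that("windowed null range matches a circular-shift surrogate", {
  rec <- noise_rec(n_subjects = 5L, n_channels = 6L, n = 5000L, fs = 250,
                   seed = 41L)
  flt_holdout <- fit_corrca(compute_covariances(
    noise_rec(n_subjects = 5L, n_channels = 6L, n = 5000L, fs = 250,
              seed = 42L)), gamma = 0.1)
  ts <- time_resolved_isc(rec, flt_holdout, K = 3)
  # surrogate: circularly shift each subject independently, recompute
  shifts <- iscpipe:::with_seed(43L, sample(500:4500, 5))
  rec_s <- rec
  rec_s$data <- Map(function(X, s)
    X[, c((s + 1):ncol(X), 1:s), drop = FALSE], rec$data, shifts)
  ts_s <- time_resolved_isc(rec_s, flt_holdout, K = 3)
  q <- quantile(ts$windows, c(0.025, 0.975))
  q_s <- quantile(ts_s$windows, c(0.025, 0.975))
  expect_lt(max(abs(q - q_s)), 0.15)
})
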