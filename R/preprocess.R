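## The EEG preprocessing chain.
##
## Stage order is fixed: band-pass filter -> bad-channel zeroing -> ICA
## ocular cleanup -> outlier zeroing -> z-scoring, with clip-onset excision
## carried as a boolean mask (never a deletion) so that every downstream
## stage -- windowing, movement annotation, ALD -- excludes exactly the
## same samples.  Bad channels are zeroed rather than interpolated so they
## cannot contaminate the covariance matrices the component analysis rests
## on.

empty_report <- function(rec) {
  list(zeroed_channels = setNames(vector("list", n_subjects(rec)), rec$subjects),
       zeroed_sample_fraction = NULL,
       removed_ica_components = setNames(vector("list", n_subjects(rec)),
                                         rec$subjects),
       excised_mask = NULL, log = character())
}

#' Zero-phase band-pass filter a recording
#'
#' @param rec A [multi_subject_recording()].
#' @param hp High-pass cutoff in Hz (default 1).
#' @param lp Low-pass cutoff in Hz (default 50).
#' @param order Butterworth order per section (default 4).
#' @return Filtered recording, same shape.
#' @export
bandpass <- function(rec, hp = 1, lp = 50, order = 4L) {
  stopifnot(inherits(rec, "multi_subject_recording"))
  if (!(hp > 0 && hp < lp && lp < rec$fs / 2))
    stop("need 0 < hp < lp < fs/2")
  map_channels(rec, function(x) bandpass_vector(x, hp, lp, rec$fs, order))
}

#' Zero channels with outlying average power
#'
#' A channel is flagged when its average power exceeds the mean channel
#' power by `k_sd` SDs (statistics per subject, across channels, one
#' pass).  Flagged channels are replaced by all-zero samples so they drop
#' out of the covariance computation.
#'
#' @param rec A [multi_subject_recording()].
#' @param k_sd Threshold in SDs of channel power (default 4).
#' @return List with `recording` and `report`.
#' @export
zero_bad_channels <- function(rec, k_sd = 4) {
  stopifnot(inherits(rec, "multi_subject_recording"), n_channels(rec) >= 2)
  report <- empty_report(rec)
  for (k in seq_len(n_subjects(rec))) {
    pow <- rowMeans(rec$data[[k]]^2)
    s <- sd(pow)
    bad <- if (is.na(s) || s == 0) integer(0) else
      which(pow > mean(pow) + k_sd * s)
    if (length(bad)) {
      rec$data[[k]][bad, ] <- 0
      report$zeroed_channels[[k]] <- bad
      report$log <- c(report$log, sprintf(
        "subject %s: zeroed channel(s) %s", rec$subjects[k],
        paste(bad, collapse = ",")))
    } else report$zeroed_channels[[k]] <- integer(0)
  }
  list(recording = rec, report = report)
}

#' Remove ocular artifacts by ICA
#'
#' Runs fastICA per subject and subtracts components whose time course
#' correlates with a frontal-channel EOG surrogate above `r_thresh` in
#' absolute value.  The surrogate is the mean of the frontal channels
#' low-passed at 8 Hz: ocular artifacts are slow, and restricting the
#' surrogate to the blink band keeps broadband noise components from
#' correlating with it spuriously.  An explicit per-subject component
#' list overrides the automatic selection; an empty list is the identity
#' transform.
#'
#' @param rec A [multi_subject_recording()].
#' @param components Optional list (one integer vector per subject) of
#'   component indices to remove; `NULL` for automatic selection.
#' @param eog_channels Channel indices or labels of the EOG surrogate;
#'   defaults to Fp1/Fp2 when present, else the first two channels.
#' @param r_thresh Absolute-correlation threshold for automatic selection
#'   (default 0.7).
#' @param n_components Number of ICA components (default: data rank, capped
#'   at channel count).
#' @param seed Seed for the ICA initialization.
#' @return List with `recording` and `report` (removed components and
#'   convergence info per subject).
#' @export
remove_eye_artifacts <- function(rec, components = NULL, eog_channels = NULL,
                                 r_thresh = 0.7, n_components = NULL,
                                 seed = 1L) {
  stopifnot(inherits(rec, "multi_subject_recording"))
  report <- empty_report(rec)
  if (is.null(eog_channels)) {
    eog_channels <- which(rec$channel_labels %in% c("Fp1", "Fp2"))
    if (length(eog_channels) == 0) eog_channels <- 1:2
  } else if (is.character(eog_channels)) {
    eog_channels <- match(eog_channels, rec$channel_labels)
  }
  for (k in seq_len(n_subjects(rec))) {
    X <- rec$data[[k]]
    manual <- if (!is.null(components)) components[[k]] else NULL
    if (!is.null(manual) && length(manual) == 0) {
      report$removed_ica_components[[k]] <- integer(0)
      next
    }
    live <- which(apply(X, 1, function(r) any(r != 0)))
    if (length(live) < 2) { report$removed_ica_components[[k]] <- integer(0); next }
    ic <- fast_ica(X[live, , drop = FALSE], n_components = n_components,
                   seed = seed)
    if (!ic$converged)
      report$log <- c(report$log, sprintf(
        "subject %s: ICA did not converge (seed %d, %d iterations)",
        rec$subjects[k], seed, ic$iterations))
    rm_idx <- if (!is.null(manual)) manual else {
      eog <- colMeans(X[intersect(eog_channels, live), , drop = FALSE])
      lpf <- butter_design(4, min(8, 0.4 * rec$fs), rec$fs, "low")
      eog <- filtfilt_ba(lpf$b, lpf$a, eog, pad = ceiling(rec$fs))
      r <- suppressWarnings(apply(ic$S, 1, cor, y = eog))
      which(!is.na(r) & abs(r) > r_thresh)
    }
    if (length(rm_idx)) {
      artifact <- ic$mixing[, rm_idx, drop = FALSE] %*%
        ic$S[rm_idx, , drop = FALSE]
      X[live, ] <- X[live, , drop = FALSE] - artifact
      rec$data[[k]] <- X
    }
    report$removed_ica_components[[k]] <- rm_idx
  }
  list(recording = rec, report = report)
}

## Outlier threshold readings; the magnitude-based wording is ambiguous,
## so the rule is configurable (default: |x| > mean|x| + k*SD(|x|)).
outlier_threshold <- function(x, k_sd, rule) {
  switch(rule,
         mean_abs_plus_sd = mean(abs(x)) + k_sd * sd(abs(x)),
         sd_abs = k_sd * sd(abs(x)),
         sd_raw = k_sd * sd(x),
         stop("unknown outlier rule: ", rule))
}

#' Zero outlier samples with a padding margin
#'
#' Samples whose magnitude exceeds the channel's outlier threshold are
#' zeroed together with every sample within `pad_ms` before and after.
#' Thresholds are computed from the data before any zeroing.
#'
#' @param rec A [multi_subject_recording()].
#' @param k_sd Threshold multiplier (default 3).
#' @param pad_ms Padding in milliseconds on each side (default 40).
#' @param rule One of `"mean_abs_plus_sd"` (default), `"sd_abs"`,
#'   `"sd_raw"`.
#' @return List with `recording` and `report` (per-subject-channel zeroed
#'   fraction).
#' @export
zero_outliers <- function(rec, k_sd = 3, pad_ms = 40,
                          rule = "mean_abs_plus_sd") {
  stopifnot(inherits(rec, "multi_subject_recording"), pad_ms >= 0)
  pad <- as.integer(round(pad_ms / 1000 * rec$fs))
  report <- empty_report(rec)
  frac <- matrix(0, n_subjects(rec), n_channels(rec),
                 dimnames = list(rec$subjects, rec$channel_labels))
  for (k in seq_len(n_subjects(rec))) {
    X <- rec$data[[k]]
    for (ch in seq_len(nrow(X))) {
      x <- X[ch, ]
      if (all(x == 0)) next
      thr <- outlier_threshold(x, k_sd, rule)
      hits <- which(abs(x) > thr)
      if (length(hits) == 0) next
      mask <- rep(FALSE, length(x))
      for (h in hits)
        mask[max(1L, h - pad):min(length(x), h + pad)] <- TRUE
      X[ch, mask] <- 0
      frac[k, ch] <- mean(mask)
    }
    rec$data[[k]] <- X
  }
  report$zeroed_sample_fraction <- frac
  list(recording = rec, report = report)
}

#' Z-score every channel of every subject
#'
#' Mean and SD are computed over non-excised samples only, then applied to
#' the whole channel; a channel with zero SD (e.g. a zeroed bad channel)
#' is left untouched rather than divided by zero.
#'
#' @param rec A [multi_subject_recording()].
#' @param excised Optional logical per-sample mask (`TRUE` = excised) from
#'   [excise_onsets()].
#' @return The z-scored recording.
#' @export
zscore_recording <- function(rec, excised = NULL) {
  stopifnot(inherits(rec, "multi_subject_recording"))
  keep <- if (is.null(excised)) rep(TRUE, n_rec_samples(rec)) else !excised
  stopifnot(length(keep) == n_rec_samples(rec))
  map_channels(rec, function(x) {
    m <- mean(x[keep]); s <- sd(x[keep])
    if (is.na(s) || s < 1e-12) x else (x - m) / s
  })
}

#' Mask the first seconds of every clip
#'
#' Scene transitions inflate ISC for reasons unrelated to stimulus
#' content, so the first `skip` seconds of each clip are excised.  The
#' data are untouched; the returned mask is honoured by every downstream
#' stage (z-scoring statistics, windowed ISC, movement annotation, ALD).
#'
#' @param rec A [multi_subject_recording()].
#' @param skip Seconds to excise from each clip onset (default 5).
#' @return Logical vector, one element per sample, `TRUE` where excised.
#' @export
excise_onsets <- function(rec, skip = 5) {
  stopifnot(inherits(rec, "multi_subject_recording"), skip >= 0)
  n <- n_rec_samples(rec)
  mask <- rep(FALSE, n)
  if (skip == 0) return(mask)
  for (i in seq_len(nrow(rec$layout))) {
    st <- rec$layout$start[i]; en <- rec$layout$end[i]
    if (en - st <= skip)
      warning(sprintf("clip %d of block %d (%.1f s) shorter than skip: fully excised",
                      rec$layout$clip[i], rec$layout$block[i], en - st))
    idx <- window_sample_idx(st, min(skip, en - st), rec$fs, n)
    mask[idx] <- TRUE
  }
  mask
}

#' Run the full preprocessing chain
#'
#' Applies, in order: band-pass filter, bad-channel zeroing, ICA ocular
#' cleanup, outlier zeroing, z-scoring; computes the clip-onset excision
#' mask and uses it for the z-scoring statistics.
#'
#' @param rec A raw [multi_subject_recording()].
#' @param hp,lp Band-pass cutoffs in Hz.
#' @param k_sd_channels Bad-channel threshold in SDs of channel power.
#' @param k_sd_outliers Outlier threshold multiplier.
#' @param pad_ms Outlier padding (ms).
#' @param skip Clip-onset excision (s).
#' @param ica `TRUE` to run ocular ICA, `FALSE` to skip the stage.
#' @param ica_components Optional explicit component list, see
#'   [remove_eye_artifacts()].
#' @param seed Seed for the ICA stage.
#' @return List with `recording`, `excised` mask and merged `report`.
#' @export
preprocess <- function(rec, hp = 1, lp = 50, k_sd_channels = 4,
                       k_sd_outliers = 3, pad_ms = 40, skip = 5,
                       ica = TRUE, ica_components = NULL, seed = 1L) {
  excised <- excise_onsets(rec, skip)
  rec <- bandpass(rec, hp, lp)
  st1 <- zero_bad_channels(rec, k_sd_channels)
  st2 <- if (ica)
    remove_eye_artifacts(st1$recording, components = ica_components,
                         seed = seed)
  else list(recording = st1$recording, report = empty_report(rec))
  st3 <- zero_outliers(st2$recording, k_sd_outliers, pad_ms)
  out <- zscore_recording(st3$recording, excised)
  report <- list(zeroed_channels = st1$report$zeroed_channels,
                 removed_ica_components = st2$report$removed_ica_components,
                 zeroed_sample_fraction = st3$report$zeroed_sample_fraction,
                 excised_mask = excised,
                 log = c(st1$report$log, st2$report$log, st3$report$log))
  list(recording = out, excised = excised, report = report)
}
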