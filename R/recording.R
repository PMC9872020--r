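## Core containers: the clip layout and the aligned multi-subject recording.

#' Clip layout of a block-structured stimulus
#'
#' Describes how short clips tile the (concatenated) stimulus timeline.
#' Clips within a block are contiguous, non-overlapping and ordered; times
#' are seconds from the start of the recording, half-open `[start, end)`.
#'
#' @param clip_lengths Either a numeric vector of clip lengths (seconds),
#'   recycled over blocks, or a list with one numeric vector per block.
#' @param n_blocks Number of blocks (ignored when `clip_lengths` is a list).
#' @return A `clip_layout`: data.frame with columns `block`, `clip`,
#'   `start`, `end`.
#' @examples
#' clip_layout(rep(15, 4), n_blocks = 2)
#' @export
clip_layout <- function(clip_lengths, n_blocks = 1L) {
  if (!is.list(clip_lengths))
    clip_lengths <- rep(list(as.numeric(clip_lengths)), n_blocks)
  stopifnot(all(unlist(clip_lengths) > 0))
  rows <- list()
  t0 <- 0
  for (b in seq_along(clip_lengths)) {
    len <- clip_lengths[[b]]
    ends <- t0 + cumsum(len)
    rows[[b]] <- data.frame(block = b, clip = seq_along(len),
                            start = c(t0, ends[-length(ends)]), end = ends)
    t0 <- ends[length(ends)]
  }
  out <- do.call(rbind, rows)
  class(out) <- c("clip_layout", "data.frame")
  out
}

layout_duration <- function(layout) max(layout$end)

## Block containing a time point (half-open clips).
layout_block_at <- function(layout, t) {
  i <- findInterval(t + 1e-9, layout$start)
  layout$block[pmax(i, 1L)]
}

#' Aligned multi-subject EEG recording
#'
#' One stimulus, several viewers: per-subject channels-by-samples matrices
#' that are temporally aligned, share a channel montage, a sampling rate
#' and a clip layout.
#'
#' @param data Named list of channels x samples numeric matrices, one per
#'   subject, all the same dimension.
#' @param fs Sampling rate in Hz.
#' @param layout A [clip_layout()]; defaults to a single clip spanning the
#'   recording.
#' @param channel_labels Optional channel labels (defaults to `ch01`...).
#' @return A `multi_subject_recording`.
#' @export
multi_subject_recording <- function(data, fs, layout = NULL,
                                    channel_labels = NULL) {
  stopifnot(is.list(data), length(data) >= 1, fs > 0)
  if (is.null(names(data)) || any(names(data) == ""))
    names(data) <- sprintf("sub%02d", seq_along(data))
  dims <- vapply(data, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all subjects must share channel and sample counts")
  n_ch <- dims[1, 1]; n_s <- dims[2, 1]
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%02d", seq_len(n_ch))
  stopifnot(length(channel_labels) == n_ch)
  if (is.null(layout)) layout <- clip_layout(n_s / fs)
  if (abs(layout_duration(layout) * fs - n_s) > 0.5)
    stop("sample count disagrees with clip layout duration")
  structure(list(subjects = names(data), data = data, fs = fs,
                 channel_labels = channel_labels, layout = layout),
            class = "multi_subject_recording")
}

n_subjects <- function(rec) length(rec$data)
n_channels <- function(rec) nrow(rec$data[[1]])
n_rec_samples <- function(rec) ncol(rec$data[[1]])
rec_duration <- function(rec) n_rec_samples(rec) / rec$fs

#' @export
print.multi_subject_recording <- function(x, ...) {
  cat(sprintf(
    "multi_subject_recording: %d subjects, %d channels, %d samples @ %g Hz (%.1f s, %d blocks)\n",
    n_subjects(x), n_channels(x), n_rec_samples(x), x$fs,
    rec_duration(x), max(x$layout$block)))
  invisible(x)
}

## Apply a per-channel function over every subject, preserving shape.
map_channels <- function(rec, f) {
  rec$data <- lapply(rec$data, function(m) {
    out <- t(apply(m, 1, f))
    dim(out) <- dim(m)
    out
  })
  rec
}

## Standard 32-channel 10-20 montage (frontal channels first two).
montage32 <- function() c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT9", "FC5", "FC1", "FC2",
  "FC6", "FT10", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2",
  "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")
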