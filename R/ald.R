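## Average luminance difference (ALD): a scalar index of low-level visual
## dynamics.  Per frame transition, ALD is the mean over pixels of the
## squared grayscale intensity change; per window it is max-downsampled
## onto the shared ISC grid so that it can enter the engagement model as a
## covariate.

#' Convert an RGB frame to grayscale
#'
#' Unweighted per-pixel mean of the R, G, B channels, on the 0-255 scale.
#'
#' @param frame Numeric array `height x width x 3`, values in 0-255, or an
#'   already-gray `height x width` matrix when `allow_gray = TRUE`.
#' @param allow_gray Accept a 2-D matrix unchanged (default `FALSE`).
#' @return `height x width` grayscale matrix.
#' @export
to_grayscale <- function(frame, allow_gray = FALSE) {
  d <- dim(frame)
  if (length(d) == 2) {
    if (allow_gray) return(frame)
    stop("expected an RGB array with 3 channels (set allow_gray for matrices)")
  }
  if (length(d) != 3 || d[3] != 3)
    stop("expected an RGB array with 3 channels")
  if (min(frame) < 0 || max(frame) > 255)
    stop("pixel values must lie in 0-255")
  (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
}

#' ALD of one frame transition
#'
#' @param g1,g2 Grayscale matrices of identical dimension.
#' @return Mean over pixels of `(g2 - g1)^2`.
#' @export
frame_ald <- function(g1, g2) {
  if (!identical(dim(g1), dim(g2)))
    stop("frame dimensions differ")
  mean((g2 - g1)^2)
}

#' Per-transition ALD of a grayscale frame stack
#'
#' @param stack `height x width x frames` array (gray 0-255).
#' @return Numeric vector of length `frames - 1`.
#' @export
stack_ald <- function(stack) {
  d <- dim(stack)
  stopifnot(length(d) == 3, d[3] >= 2)
  flat <- matrix(stack, d[1] * d[2], d[3])
  colMeans((flat[, -1, drop = FALSE] - flat[, -d[3], drop = FALSE])^2)
}

#' Max-downsample per-frame ALD onto the ISC window grid
#'
#' Each retained window receives the maximum per-transition ALD among the
#' transitions inside it.  Transitions in excised spans, and (by default)
#' transitions spanning a clip boundary -- which encode cuts, not motion --
#' are ignored.
#'
#' @param per_frame Per-transition ALD vector, e.g. from [stack_ald()].
#' @param grid Window grid shared with [time_resolved_isc()].
#' @param fps Video frame rate.
#' @param excised_times Optional excised spans (`start`/`end` seconds).
#' @param layout Optional [clip_layout()]; when given, transitions at clip
#'   boundaries are excluded.
#' @param exclude_boundaries Exclude clip-boundary transitions
#'   (default `TRUE`, only relevant with `layout`).
#' @return An `ald_series`: data.frame (`window`, `start`, `ald`) over
#'   retained windows, grid as attribute.
#' @export
downsample_ald <- function(per_frame, grid, fps, excised_times = NULL,
                           layout = NULL, exclude_boundaries = TRUE) {
  tt <- transition_time(seq_along(per_frame), fps)
  drop <- rep(FALSE, length(tt))
  if (!is.null(excised_times) && nrow(excised_times) > 0)
    for (i in seq_len(nrow(excised_times)))
      drop <- drop | (tt >= excised_times$start[i] & tt < excised_times$end[i])
  if (!is.null(layout) && exclude_boundaries) {
    cut_frames <- time_to_frame(layout$start[-1], fps)
    drop[cut_frames - 1L] <- TRUE          # transition into the cut frame
  }
  out <- grid[grid$retained, c("window", "start")]
  out$ald <- NA_real_
  empty <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    w <- out$window[i]
    inside <- !drop & tt >= grid$start[w] & tt < grid$end[w]
    if (!any(inside)) { empty[i] <- TRUE; next }
    out$ald[i] <- max(per_frame[inside])
  }
  if (any(empty)) {
    warning(sum(empty), " window(s) had no usable ALD transitions; dropped")
    out <- out[!empty, ]
    grid$retained[!grid$window %in% out$window] <- FALSE
  }
  structure(out, grid = grid, class = c("ald_series", "data.frame"))
}
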