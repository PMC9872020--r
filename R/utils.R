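## Shared helpers: time-base conversions and the sliding-window grid that
## every stage (ISC, movement annotation, ALD) must agree on.

#' Number of EEG samples spanned by one analysis window
#'
#' @param fs Sampling rate in Hz.
#' @param window_len Window length in seconds.
#' @return Integer sample count.
#' @examples
#' samples_per_window(500, 1.5)  # 750
#' @export
samples_per_window <- function(fs, window_len) {
  stopifnot(fs > 0, window_len > 0)
  as.integer(round(fs * window_len))
}

#' Sliding-window grid over a recording
#'
#' Builds the canonical window grid used by the time-resolved ISC and, by
#' reference, by the movement-annotation and ALD stages.  Windows are
#' half-open intervals `[start, start + window_len)` in seconds from the
#' start of the recording; consecutive starts differ by `hop`
#' (`hop = window_len - overlap`).
#'
#' @param duration Recording duration in seconds.
#' @param window_len Window length in seconds (default 1.5).
#' @param hop Hop between window starts in seconds (default 0.3,
#'   i.e. 1.2 s overlap at the default window length).
#' @return A data.frame with columns `window`, `start`, `end` and a
#'   logical `retained` column (all `TRUE` until excision is applied).
#' @export
window_grid <- function(duration, window_len = 1.5, hop = 0.3) {
  stopifnot(duration > 0, window_len > 0, hop > 0)
  if (window_len <= hop)
    stop("window_len must exceed hop (windows must overlap)")
  if (window_len > duration)
    stop("window longer than recording")
  n <- floor((duration - window_len) / hop + 1e-9) + 1L
  starts <- (seq_len(n) - 1L) * hop
  data.frame(window = seq_len(n), start = starts, end = starts + window_len,
             retained = TRUE)
}

## Sample indices (1-based) covered by one window.
window_sample_idx <- function(start, window_len, fs, n_samples) {
  first <- floor(start * fs + 1e-9) + 1L
  idx <- first:(first + samples_per_window(fs, window_len) - 1L)
  idx[idx <= n_samples]
}

## 1-based frame index holding time point t (frame 0 = first frame).
time_to_frame <- function(t, fps) floor(t * fps + 1e-9) + 1L

## Time (seconds) of the transition between frames j and j+1 (1-based j):
## the instant frame j+1 appears.
transition_time <- function(j, fps) j / fps

## Fraction-safe mean that returns NA for empty input instead of NaN.
mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

## Assert two window grids are the same grid (starts, lengths, drops).
assert_same_grid <- function(a, b, what = "window grids") {
  if (nrow(a) != nrow(b) ||
      max(abs(a$start - b$start)) > 1e-9 ||
      !identical(a$retained, b$retained))
    stop(what, " do not match: stages must share one grid")
  invisible(TRUE)
}

## Central finite-difference gradient and Hessian (used by the
## Satterthwaite approximation; kept dependency-free).
fd_grad <- function(f, x, h = NULL) {
  if (is.null(h)) h <- pmax(abs(x) * 1e-4, 1e-6)
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h[i]
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

fd_hess <- function(f, x, h = NULL) {
  if (is.null(h)) h <- pmax(abs(x) * 1e-3, 1e-5)
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- rep(0, n); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < n) for (j in (i + 1):n) {
      ej <- rep(0, n); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}
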