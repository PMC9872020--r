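## Dual-threshold movement annotation from pose keypoints.
##
## A limb "moves" between two consecutive frames when the Euclidean
## displacement of any of its joints lies strictly above theta_low (which
## rejects camera jitter) and at or below theta_high (which rejects scene
## cuts, where everything jumps at once).  Frame-level arm/leg indicators
## are then aggregated onto the ISC window grid.

#' Per-transition joint displacements of a keypoint track
#'
#' Euclidean distance of each joint's screen coordinates between
#' consecutive frames, per person (matched by detection index).  A joint
#' missing in either frame (confidence 0) yields `NA`.
#'
#' @param track A `keypoint_track` (see [generate_keypoints()] or
#'   [read_keypoints()]).
#' @return data.frame with columns `transition` (1-based: between frames
#'   `t` and `t + 1`), `person`, `joint`, `dist`.
#' @export
limb_displacement <- function(track) {
  stopifnot(inherits(track, "keypoint_track"))
  n_frames <- length(track$frames)
  if (n_frames < 2) stop("need at least 2 frames")
  rows <- vector("list", n_frames - 1L)
  for (t in seq_len(n_frames - 1L)) {
    p1 <- track$frames[[t]]$people
    p2 <- track$frames[[t + 1L]]$people
    np <- min(length(p1), length(p2))
    if (np == 0) { rows[[t]] <- NULL; next }
    per_person <- lapply(seq_len(np), function(p) {
      a <- p1[[p]]; b <- p2[[p]]
      joints <- intersect(rownames(a), rownames(b))
      d <- sqrt(rowSums((b[joints, 1:2, drop = FALSE] -
                         a[joints, 1:2, drop = FALSE])^2))
      d[a[joints, 3] == 0 | b[joints, 3] == 0] <- NA_real_
      data.frame(transition = t, person = p, joint = joints, dist = d,
                 row.names = NULL)
    })
    rows[[t]] <- do.call(rbind, per_person)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify frame transitions as arm / leg movement
#'
#' A transition is positive for a limb category iff any joint of that
#' category (over all persons) displaced by more than `theta_low` and at
#' most `theta_high` pixels.
#'
#' @param dists Displacement table from [limb_displacement()].
#' @param theta_low,theta_high Lower/upper displacement thresholds in px
#'   (`0 <= theta_low < theta_high`).
#' @param n_transitions Total number of transitions (defaults to the max
#'   seen in `dists`).
#' @return data.frame with columns `transition`, `arm`, `leg`.
#' @export
classify_frames <- function(dists, theta_low, theta_high,
                            n_transitions = NULL) {
  if (!(theta_low >= 0 && theta_low < theta_high))
    stop("need 0 <= theta_low < theta_high")
  if (is.null(n_transitions)) n_transitions <- max(dists$transition)
  moving <- !is.na(dists$dist) &
    dists$dist > theta_low & dists$dist <= theta_high
  arm <- leg <- rep(FALSE, n_transitions)
  is_arm <- dists$joint %in% ARM_JOINTS
  is_leg <- dists$joint %in% LEG_JOINTS
  arm_t <- unique(dists$transition[moving & is_arm])
  leg_t <- unique(dists$transition[moving & is_leg])
  arm[arm_t] <- TRUE
  leg[leg_t] <- TRUE
  data.frame(transition = seq_len(n_transitions), arm = arm, leg = leg)
}

#' Aggregate frame-level indicators onto the ISC window grid
#'
#' Each retained window receives one category from
#' `{neither, arm, leg, both}`: a window is arm-positive when at least
#' `rule_fraction` of its retained frame transitions are arm-positive
#' (likewise leg), and `both` means arm-positive and leg-positive.
#' Transitions inside excised spans are ignored; a retained window left
#' with no transitions is dropped and flagged.
#'
#' @param flags Frame-transition table from [classify_frames()].
#' @param grid Window grid shared with the [time_resolved_isc()] output.
#' @param fps Video frame rate.
#' @param excised_times Optional data.frame of excised spans with columns
#'   `start`, `end` (seconds), e.g. from [mask_to_spans()].
#' @param rule_fraction Fraction of positive transitions required
#'   (default 0.25).
#' @param theta Optional length-2 vector recording the thresholds used.
#' @return A `movement_series`: data.frame (`window`, `start`, `category`,
#'   `arm`, `leg`) over retained windows, with the grid and thresholds as
#'   attributes.
#' @export
window_categories <- function(flags, grid, fps, excised_times = NULL,
                              rule_fraction = 0.25, theta = NULL) {
  tt <- transition_time(flags$transition, fps)
  drop <- rep(FALSE, length(tt))
  if (!is.null(excised_times) && nrow(excised_times) > 0)
    for (i in seq_len(nrow(excised_times)))
      drop <- drop | (tt >= excised_times$start[i] & tt < excised_times$end[i])
  out <- grid[grid$retained, c("window", "start")]
  out$category <- factor(rep("neither", nrow(out)), levels = MOVEMENT_LEVELS)
  out$arm <- out$leg <- FALSE
  empty <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    w <- out$window[i]
    inside <- !drop & tt >= grid$start[w] & tt < grid$end[w]
    if (!any(inside)) { empty[i] <- TRUE; next }
    a <- mean(flags$arm[inside]) >= rule_fraction
    l <- mean(flags$leg[inside]) >= rule_fraction
    out$arm[i] <- a; out$leg[i] <- l
    out$category[i] <- if (a && l) "both" else if (a) "arm" else
      if (l) "leg" else "neither"
  }
  if (any(empty)) {
    warning(sum(empty), " window(s) had no retained frame transitions; dropped")
    out <- out[!empty, ]
    grid$retained[!grid$window %in% out$window] <- FALSE
  }
  structure(out, grid = grid, theta = theta, rule_fraction = rule_fraction,
            class = c("movement_series", "data.frame"))
}

#' Excised spans (seconds) from a per-sample mask
#'
#' @param excised Logical per-sample mask (`TRUE` = excised).
#' @param fs Sampling rate in Hz.
#' @return data.frame with `start`, `end` columns in seconds.
#' @export
mask_to_spans <- function(excised, fs) {
  r <- rle(excised)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep] / fs, end = ends[keep] / fs)
}
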