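## Synthetic multi-subject EEG, pose-keypoint tracks and frame stacks with
## known ground truth.
##
## The generative model is deliberately minimal: every subject shares one
## band-limited latent source s(t) whose amplitude is modulated by the
## movement content of the stimulus,
##
##     X_k(t) = mixing * g(t) * s(t) + noise_sd * eps_k(t),
##     g(t)   = base_gain + movement_gains[category(t)],
##
## with eps_k independent across subjects and channels.  Movement gates the
## *shared* signal only, never the subject noise, so inter-subject coupling
## (and hence ISC) is the one mechanism linking stimulus movement to the
## measured outcome.

## Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the study design at reduced scale: 8 viewers, a
#' 32-channel montage, block-structured silent clips, and additive gain
#' boosts on the shared source when the (virtual) stimulus shows arm, leg
#' or simultaneous arm-and-leg movement.  Event durations follow the
#' reported movement statistics of the stimuli (arm movements are short,
#' about 1.4 s on average; leg movements long, about 9 s).
#'
#' @param n_subjects Number of viewers (>= 2; ISC is undefined otherwise).
#' @param n_channels EEG channels (default 32).
#' @param fs EEG sampling rate in Hz (default 250; the study used 500 --
#'   halved here to keep simulations desk-sized).
#' @param n_blocks Number of video blocks.
#' @param clip_lengths Clip lengths in seconds within each block (vector,
#'   recycled over blocks, or list of vectors).
#' @param duration Total duration in seconds; derived from the layout when
#'   `NULL`, validated against it otherwise.
#' @param mixing Channel-loading vector of the latent source; default is a
#'   smooth posterior-weighted topography.
#' @param base_gain Shared-signal amplitude during movement-free scenes.
#' @param movement_gains Named additive gains `c(arm=, leg=, both=)`.
#' @param noise_sd Per-channel noise SD.
#' @param fps Video frame rate (default 25).
#' @param event_rates Means (seconds) of the exponential event/gap
#'   processes: `arm_len`, `arm_gap`, `leg_len`, `leg_gap`.
#' @param artifact_spec Optional list enabling artifact injection:
#'   `blink_rate` (/s), `blink_amp`, `bad_channel` (index),
#'   `bad_scale`, `spike_rate` (/s/subject), `spike_amp`.
#' @param seed RNG seed; the whole generator is a pure function of the
#'   configuration.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 8L, n_channels = 32L, fs = 250,
                         n_blocks = 2L, clip_lengths = rep(15, 4),
                         duration = NULL, mixing = NULL, base_gain = 1,
                         movement_gains = c(arm = 0.5, leg = 0.5, both = 1),
                         noise_sd = 1, fps = 25,
                         event_rates = c(arm_len = 1.36, arm_gap = 4,
                                         leg_len = 9.2, leg_gap = 20),
                         artifact_spec = NULL, seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2: ISC is undefined for one subject")
  stopifnot(fs > 0, fps > 0, n_channels >= 2, base_gain >= 0, noise_sd >= 0)
  movement_gains <- movement_gains[c("arm", "leg", "both")]
  if (anyNA(movement_gains) || any(movement_gains < 0))
    stop("movement_gains must supply non-negative arm, leg and both gains")
  layout <- clip_layout(clip_lengths, n_blocks)
  if (is.null(duration)) duration <- layout_duration(layout)
  if (abs(duration - layout_duration(layout)) > 1e-9)
    stop("clip_lengths must sum to duration")
  if (is.null(mixing)) {
    ch <- seq_len(n_channels)
    # occipital-weighted bump plus a floor loading on every channel
    mixing <- exp(-((ch - 0.85 * n_channels) / (0.2 * n_channels))^2) + 0.15
  }
  stopifnot(length(mixing) == n_channels)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels), fs = fs,
                 n_blocks = as.integer(n_blocks), layout = layout,
                 duration = duration, mixing = as.numeric(mixing),
                 base_gain = base_gain, movement_gains = movement_gains,
                 noise_sd = noise_sd, fps = fps, event_rates = event_rates,
                 artifact_spec = artifact_spec, seed = as.integer(seed)),
            class = "synth_config")
}

## Alternating gap/event renewal process covering [0, duration].
simulate_events <- function(duration, gap_mean, len_mean) {
  t <- rexp(1, 1 / gap_mean)  # start inside a gap
  out <- list()
  while (t < duration) {
    len <- rexp(1, 1 / len_mean)
    out[[length(out) + 1L]] <- c(start = t, end = min(t + len, duration))
    t <- t + len + rexp(1, 1 / gap_mean)
  }
  if (length(out) == 0) return(data.frame(start = numeric(), end = numeric()))
  as.data.frame(do.call(rbind, out))
}

#' Ground-truth movement track of a synthetic stimulus
#'
#' Per-frame movement category plus the underlying event log.  Deterministic
#' from `cfg$seed`, and shared by [generate_eeg()] and
#' [generate_keypoints()] so the EEG gain track and the keypoint motion
#' describe the same virtual stimulus.
#'
#' @param cfg A [synth_config()].
#' @return List with `category` (factor per frame), `arm`, `leg`
#'   (per-frame logicals) and `events` (data.frame kind/start/end).
#' @export
movement_track <- function(cfg) {
  with_seed(cfg$seed, {
    n_frames <- round(cfg$duration * cfg$fps)
    arm_ev <- simulate_events(cfg$duration, cfg$event_rates[["arm_gap"]],
                              cfg$event_rates[["arm_len"]])
    leg_ev <- simulate_events(cfg$duration, cfg$event_rates[["leg_gap"]],
                              cfg$event_rates[["leg_len"]])
    mid <- (seq_len(n_frames) - 0.5) / cfg$fps
    in_any <- function(t, ev) {
      if (nrow(ev) == 0) return(rep(FALSE, length(t)))
      Reduce(`|`, lapply(seq_len(nrow(ev)),
                         function(i) t >= ev$start[i] & t < ev$end[i]))
    }
    arm <- in_any(mid, arm_ev)
    leg <- in_any(mid, leg_ev)
    category <- factor(ifelse(arm & leg, "both",
                       ifelse(arm, "arm", ifelse(leg, "leg", "neither"))),
                       levels = MOVEMENT_LEVELS)
    events <- rbind(
      if (nrow(arm_ev)) data.frame(kind = "arm", arm_ev),
      if (nrow(leg_ev)) data.frame(kind = "leg", leg_ev))
    list(category = category, arm = arm, leg = leg,
         events = if (is.null(events)) data.frame(kind = character(),
                                                  start = numeric(),
                                                  end = numeric()) else events)
  })
}

gain_track_from_categories <- function(cfg, category) {
  n_samples <- round(cfg$fs * cfg$duration)
  frame_of_sample <- pmin(time_to_frame((seq_len(n_samples) - 1) / cfg$fs,
                                        cfg$fps), length(category))
  extra <- c(neither = 0, cfg$movement_gains)
  cfg$base_gain + unname(extra[as.character(category)[frame_of_sample]])
}

#' Generate a synthetic multi-subject EEG recording
#'
#' @param cfg A [synth_config()].
#' @return List with `recording` (a [multi_subject_recording()]) and
#'   `truth`, the ground-truth bundle (latent source, per-sample gain
#'   track, per-frame movement categories, artifact event log).
#' @export
generate_eeg <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  track <- movement_track(cfg)
  n_samples <- round(cfg$fs * cfg$duration)
  g <- gain_track_from_categories(cfg, track$category)
  out <- with_seed(cfg$seed + 1L, {
    s <- rnorm(n_samples)
    s <- bandpass_vector(s, 1, min(15, 0.45 * cfg$fs), cfg$fs)
    s <- s / sd(s)
    shared <- outer(cfg$mixing, g * s)
    data <- vector("list", cfg$n_subjects)
    events <- list()
    for (k in seq_len(cfg$n_subjects)) {
      eps <- matrix(rnorm(cfg$n_channels * n_samples, sd = cfg$noise_sd),
                    cfg$n_channels, n_samples)
      data[[k]] <- shared + eps
    }
    spec <- cfg$artifact_spec
    if (!is.null(spec)) {
      frontal_w <- exp(-(seq_len(cfg$n_channels) - 1) / 2)
      blink_len <- max(3L, round(0.3 * cfg$fs))
      blink_shape <- sin(pi * seq_len(blink_len) / (blink_len + 1))^2
      for (k in seq_len(cfg$n_subjects)) {
        if (!is.null(spec$blink_rate) && spec$blink_rate > 0) {
          n_bl <- rpois(1, spec$blink_rate * cfg$duration)
          starts <- sort(sample.int(n_samples - blink_len, n_bl))
          blink_src <- numeric(n_samples)
          for (st in starts) {
            idx <- st:(st + blink_len - 1)
            blink_src[idx] <- blink_src[idx] + spec$blink_amp * blink_shape
            events[[length(events) + 1L]] <-
              data.frame(type = "blink", subject = k, channel = NA_integer_,
                         sample = st)
          }
          data[[k]] <- data[[k]] + outer(frontal_w, blink_src)
          attr(data[[k]], "blink_source") <- blink_src
        }
        if (!is.null(spec$spike_rate) && spec$spike_rate > 0) {
          n_sp <- rpois(1, spec$spike_rate * cfg$duration)
          if (n_sp > 0) {
            chs <- sample.int(cfg$n_channels, n_sp, replace = TRUE)
            pos <- sample.int(n_samples, n_sp)
            amp <- spec$spike_amp * sample(c(-1, 1), n_sp, replace = TRUE)
            for (i in seq_len(n_sp)) {
              data[[k]][chs[i], pos[i]] <- data[[k]][chs[i], pos[i]] + amp[i]
              events[[length(events) + 1L]] <-
                data.frame(type = "spike", subject = k, channel = chs[i],
                           sample = pos[i])
            }
          }
        }
      }
      if (!is.null(spec$bad_channel)) {
        k <- if (is.null(spec$bad_subject)) 1L else spec$bad_subject
        sc <- if (is.null(spec$bad_scale)) 20 else spec$bad_scale
        data[[k]][spec$bad_channel, ] <- sc * data[[k]][spec$bad_channel, ]
        events[[length(events) + 1L]] <-
          data.frame(type = "bad_channel", subject = k,
                     channel = spec$bad_channel, sample = NA_integer_)
      }
    }
    list(data = data, source = s,
         event_log = if (length(events)) do.call(rbind, events) else
           data.frame(type = character(), subject = integer(),
                      channel = integer(), sample = integer()))
  })
  labels <- if (cfg$n_channels == 32) montage32() else
    sprintf("ch%02d", seq_len(cfg$n_channels))
  rec <- multi_subject_recording(out$data, cfg$fs, cfg$layout, labels)
  truth <- structure(list(source = out$source, gain_track = g,
                          movement_track = track$category,
                          movement_events = track$events,
                          event_log = out$event_log, ald_track = NULL,
                          mixing = cfg$mixing, fs = cfg$fs, fps = cfg$fps),
                     class = "ground_truth")
  list(recording = rec, truth = truth)
}

## Base skeleton (px) for one person; roughly anatomical, arms up-screen.
base_skeleton <- function(offset_x = 0) {
  coords <- rbind(
    shoulder_l = c(140, 100), shoulder_r = c(180, 100),
    elbow_l = c(125, 140), elbow_r = c(195, 140),
    wrist_l = c(115, 180), wrist_r = c(205, 180),
    hip_l = c(150, 200), hip_r = c(170, 200),
    knee_l = c(148, 260), knee_r = c(172, 260),
    ankle_l = c(146, 320), ankle_r = c(174, 320))
  coords[, 1] <- coords[, 1] + offset_x
  coords
}

#' Generate a synthetic pose-keypoint track
#'
#' Joint coordinates jitter everywhere (camera shake), limb joints of the
#' moving category displace by `move_amp` px per frame during ground-truth
#' movement events, and every clip boundary injects a `cut_jump` px jump of
#' all joints (a scene cut).  For clean dual-threshold fixtures choose
#' `jitter_sd << theta_low < move_amp < theta_high < cut_jump`.
#'
#' @param cfg A [synth_config()].
#' @param jitter_sd Per-frame, per-axis jitter SD in px.
#' @param move_amp Per-frame displacement of moving limb joints in px.
#' @param cut_jump Displacement of all joints at scene cuts in px.
#' @param n_people Number of people on screen.
#' @return List with `track` (a `keypoint_track`) and `truth`: per-frame
#'   categories plus a per-transition table of expected arm/leg/cut labels
#'   (cut transitions are never movement, whatever the category).
#' @export
generate_keypoints <- function(cfg, jitter_sd = 0.25, move_amp = 6,
                               cut_jump = 80, n_people = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (move_amp < 0 || cut_jump < 0 || jitter_sd < 0)
    stop("amplitudes must be non-negative")
  track <- movement_track(cfg)
  n_frames <- length(track$category)
  cut_frames <- time_to_frame(cfg$layout$start[-1], cfg$fps)  # first frame of later clips
  with_seed(cfg$seed + 2L, {
    people <- lapply(seq_len(n_people) - 1L, function(p) base_skeleton(250 * p))
    frames <- vector("list", n_frames)
    put_frame <- function(coords_list) lapply(coords_list, function(m)
      cbind(m, confidence = rep(1, nrow(m))))
    frames[[1]] <- put_frame(people)
    for (f in 2:n_frames) {
      ang_arm <- runif(1, 0, 2 * pi); ang_leg <- runif(1, 0, 2 * pi)
      is_cut <- f %in% cut_frames
      cut_dir <- runif(1, 0, 2 * pi)
      people <- lapply(people, function(m) {
        m <- m + matrix(rnorm(length(m), sd = jitter_sd), nrow(m), 2)
        if (!is_cut) {
          if (track$arm[f])
            m[ARM_JOINTS, ] <- sweep(m[ARM_JOINTS, ], 2,
                                     move_amp * c(cos(ang_arm), sin(ang_arm)), `+`)
          if (track$leg[f])
            m[LEG_JOINTS, ] <- sweep(m[LEG_JOINTS, ], 2,
                                     move_amp * c(cos(ang_leg), sin(ang_leg)), `+`)
        } else {
          m <- sweep(m, 2, cut_jump * c(cos(cut_dir), sin(cut_dir)), `+`)
        }
        m
      })
      frames[[f]] <- put_frame(people)
    }
    kt <- structure(list(fps = cfg$fps, frames = lapply(frames, function(pp)
      list(people = pp))), class = "keypoint_track")
    tt <- data.frame(
      transition = seq_len(n_frames - 1L),
      arm = track$arm[-1] & !(seq_len(n_frames)[-1] %in% cut_frames),
      leg = track$leg[-1] & !(seq_len(n_frames)[-1] %in% cut_frames),
      cut = seq_len(n_frames)[-1] %in% cut_frames)
    list(track = kt,
         truth = list(category = track$category, events = track$events,
                      transitions = tt, cut_frames = cut_frames))
  })
}

#' Generate a synthetic grayscale frame stack with known ALD
#'
#' Each clip has its own base luminance; a global per-frame luminance
#' modulation produces a known average luminance difference between
#' consecutive frames, recorded (by an independent per-pixel loop) in the
#' returned `ald_track`.
#'
#' @param cfg A [synth_config()].
#' @param height,width Frame dimensions in px (>= 1).
#' @param mod_sd SD of the per-frame global luminance modulation.
#' @return List with `stack` (height x width x frames array, gray 0-255)
#'   and `ald_track` (length frames - 1).
#' @export
generate_frames <- function(cfg, height = 16L, width = 16L, mod_sd = 3) {
  stopifnot(inherits(cfg, "synth_config"), height >= 1, width >= 1)
  n_frames <- round(cfg$duration * cfg$fps)
  with_seed(cfg$seed + 3L, {
    pattern <- matrix(runif(height * width, -20, 20), height, width)
    frame_time <- (seq_len(n_frames) - 1) / cfg$fps
    clip_idx <- findInterval(frame_time + 1e-9, cfg$layout$start)
    clip_base <- runif(nrow(cfg$layout), 60, 200)
    modul <- rnorm(n_frames, sd = mod_sd)
    stack <- array(0, dim = c(height, width, n_frames))
    for (f in seq_len(n_frames)) {
      fr <- clip_base[clip_idx[f]] + modul[f] + pattern
      stack[, , f] <- pmin(pmax(fr, 0), 255)
    }
    ald <- numeric(n_frames - 1L)
    for (f in seq_len(n_frames - 1L)) {       # plain loop: independent record
      acc <- 0
      for (i in seq_len(height)) for (j in seq_len(width))
        acc <- acc + (stack[i, j, f + 1L] - stack[i, j, f])^2
      ald[f] <- acc / (height * width)
    }
    list(stack = stack, ald_track = ald)
  })
}
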