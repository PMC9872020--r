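## On-disk formats.  Everything is plain text:
##  - EEG "container": a directory with meta.json (subjects, fs, labels,
##    clip layout) plus one TSV matrix (samples x channels) per subject;
##    the plain numeric-matrix fallback is a bare TSV plus explicit fs.
##  - keypoints: the pose-estimation JSON dialect -- per-frame files each
##    holding a "people" array with a flat [x1,y1,c1,x2,y2,c2,...] keypoint
##    list -- or one consolidated JSON with a "frames" array.
##  - frame stacks: frames.tsv (one row per frame, pixels column-major)
##    with a JSON sidecar giving the dimensions.

KEYPOINT_ORDER <- c(ARM_JOINTS, LEG_JOINTS)

#' Write a multi-subject recording to the repo-standard container
#'
#' @param rec A [multi_subject_recording()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "multi_subject_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(subjects = rec$subjects, fs = rec$fs,
               channel_labels = rec$channel_labels,
               layout = as.data.frame(rec$layout))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  for (k in seq_along(rec$data))
    data.table::fwrite(data.table::as.data.table(t(rec$data[[k]])),
                       file.path(dir, sprintf("%s.tsv", rec$subjects[k])),
                       sep = "\t")
  invisible(dir)
}

#' Read a multi-subject recording from the container format
#'
#' @param dir Directory written by [write_recording()].
#' @return A [multi_subject_recording()].
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  layout <- as.data.frame(meta$layout)
  class(layout) <- c("clip_layout", "data.frame")
  data <- lapply(meta$subjects, function(s)
    t(as.matrix(data.table::fread(file.path(dir, sprintf("%s.tsv", s))))))
  names(data) <- meta$subjects
  multi_subject_recording(data, meta$fs, layout, meta$channel_labels)
}

#' Read plain numeric-matrix EEG files
#'
#' The fallback input format: one delimited channels-in-columns matrix per
#' subject, no header metadata.
#'
#' @param files Character vector of file paths (one per subject).
#' @param fs Sampling rate in Hz.
#' @param layout Optional [clip_layout()].
#' @param channel_labels Optional channel labels.
#' @return A [multi_subject_recording()].
#' @export
read_matrix_recording <- function(files, fs, layout = NULL,
                                  channel_labels = NULL) {
  data <- lapply(files, function(f) t(as.matrix(data.table::fread(f))))
  names(data) <- tools::file_path_sans_ext(basename(files))
  multi_subject_recording(data, fs, layout, channel_labels)
}

person_to_flat <- function(m) {
  m <- m[KEYPOINT_ORDER, , drop = FALSE]
  as.numeric(t(m))
}

flat_to_person <- function(v) {
  m <- matrix(as.numeric(v), ncol = 3, byrow = TRUE)
  rownames(m) <- KEYPOINT_ORDER[seq_len(nrow(m))]
  colnames(m) <- c("x", "y", "confidence")
  m
}

#' Write a keypoint track as pose-JSON
#'
#' @param track A `keypoint_track`.
#' @param path Output path: with `per_frame = FALSE` (default) one
#'   consolidated JSON file; with `per_frame = TRUE` a directory of
#'   `frame_%06d_keypoints.json` files.
#' @param per_frame Write one file per frame.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(track, path, per_frame = FALSE) {
  stopifnot(inherits(track, "keypoint_track"))
  frame_obj <- function(fr) list(people = lapply(fr$people, function(p)
    list(pose_keypoints_2d = person_to_flat(p))))
  if (per_frame) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(fps = track$fps),
                         file.path(path, "track_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    for (f in seq_along(track$frames))
      jsonlite::write_json(frame_obj(track$frames[[f]]),
                           file.path(path, sprintf("frame_%06d_keypoints.json",
                                                   f - 1L)),
                           auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(
      list(fps = track$fps, frames = lapply(track$frames, frame_obj)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a keypoint track from pose-JSON
#'
#' Accepts either the consolidated dialect or a directory of per-frame
#' files (detected automatically).
#'
#' @param path File or directory from [write_keypoints()].
#' @param fps Frame rate override (required for per-frame directories that
#'   carry no `track_meta.json`).
#' @return A `keypoint_track`.
#' @export
read_keypoints <- function(path, fps = NULL) {
  parse_frame <- function(fr) list(people = lapply(fr$people, function(p)
    flat_to_person(unlist(p$pose_keypoints_2d))))
  if (dir.exists(path)) {
    meta_f <- file.path(path, "track_meta.json")
    if (is.null(fps)) {
      if (!file.exists(meta_f))
        stop("per-frame keypoint directory without track_meta.json: give fps")
      fps <- jsonlite::read_json(meta_f)$fps
    }
    files <- sort(list.files(path, pattern = "_keypoints\\.json$",
                             full.names = TRUE))
    frames <- lapply(files, function(f)
      parse_frame(jsonlite::read_json(f, simplifyVector = FALSE)))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    fps <- obj$fps
    frames <- lapply(obj$frames, parse_frame)
  }
  structure(list(fps = fps, frames = frames), class = "keypoint_track")
}

#' Write a grayscale frame stack
#'
#' @param stack `height x width x frames` array.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_frames <- function(stack, dir) {
  d <- dim(stack)
  stopifnot(length(d) == 3)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(height = d[1], width = d[2], n_frames = d[3]),
                       file.path(dir, "frames_meta.json"), auto_unbox = TRUE)
  flat <- t(matrix(stack, d[1] * d[2], d[3]))
  data.table::fwrite(data.table::as.data.table(flat),
                     file.path(dir, "frames.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a grayscale frame stack written by [write_frames()]
#'
#' @param dir Directory holding `frames_meta.json` and `frames.tsv`.
#' @return `height x width x frames` array.
#' @export
read_frames <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "frames_meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(data.table::fread(file.path(dir, "frames.tsv")))
  array(t(flat), dim = c(meta$height, meta$width, meta$n_frames))
}

#' Convert between input dialects
#'
#' Recognized conversions: `container` <-> `matrix` (EEG),
#' `consolidated` <-> `per_frame` (pose JSON).  Conversions are lossless
#' where the target can represent the source; converting a container to
#' bare matrices drops the metadata and refuses unless `force = TRUE`.
#'
#' @param path Input path.
#' @param from,to Dialect names.
#' @param out Output path.
#' @param fs,layout Needed when reading bare matrices.
#' @param force Allow lossy conversions.
#' @return `out`, invisibly.
#' @export
convert_io <- function(path, from, to, out, fs = NULL, layout = NULL,
                       force = FALSE) {
  key <- paste(from, to, sep = "->")
  switch(key,
    "container->matrix" = {
      if (!force)
        stop("container->matrix drops metadata (fs, layout, labels); ",
             "use force = TRUE")
      rec <- read_recording(path)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_along(rec$data))
        data.table::fwrite(data.table::as.data.table(t(rec$data[[k]])),
                           file.path(out, sprintf("%s.tsv", rec$subjects[k])),
                           sep = "\t")
    },
    "matrix->container" = {
      files <- if (dir.exists(path))
        list.files(path, pattern = "\\.tsv$", full.names = TRUE) else path
      if (is.null(fs)) stop("matrix->container needs fs")
      write_recording(read_matrix_recording(files, fs, layout), out)
    },
    "consolidated->per_frame" = write_keypoints(read_keypoints(path), out,
                                                per_frame = TRUE),
    "per_frame->consolidated" = write_keypoints(read_keypoints(path), out,
                                                per_frame = FALSE),
    stop("unknown conversion: ", key))
  invisible(out)
}

## Small helpers for stage tables.
write_stage_table <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), unlist(meta)), con)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
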