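## End-to-end orchestration: simulate (or load) -> preprocess -> CorrCA /
## time-resolved ISC -> movement annotation -> ALD -> engagement model ->
## report.  The window grid is computed once by the ISC stage and passed
## by reference to the annotation and ALD stages, so their alignment is
## structural, not conventional.  Every run is a pure function of the
## config (including its seed): identical configs give byte-identical
## stage tables.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one declarative object:
#' preprocessing thresholds, CorrCA regularization, the window geometry,
#' annotation thresholds and the model options, plus the synthetic-data
#' configuration used when `simulate = TRUE`.
#'
#' @param synth A [synth_config()] (used when `simulate = TRUE`).
#' @param simulate Generate inputs with the synthetic module (default
#'   `TRUE`); otherwise `input_dir` must name a recording container.
#' @param input_dir,keypoints_path,frames_dir Input paths when
#'   `simulate = FALSE`.
#' @param groups Named subject-to-group vector; when `NULL` under
#'   simulation, the first half of subjects are `"children"`, the rest
#'   `"adults"`.
#' @param hp,lp Band-pass cutoffs (Hz).
#' @param k_sd_channels,k_sd_outliers,pad_ms,skip Preprocessing knobs.
#' @param ica Run the ICA stage (default `FALSE` for synthetic runs --
#'   there is nothing ocular to remove unless artifacts are injected).
#' @param gamma CorrCA shrinkage weight.
#' @param n_components Components kept by CorrCA.
#' @param window_len,hop Window geometry in seconds.
#' @param k_sum Components summed into ISC (K).
#' @param theta_low,theta_high Annotation thresholds (px/frame).
#' @param rule_fraction Window-labeling rule fraction.
#' @param df_method Mixed-model df method.
#' @param seed Master seed of the run.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), simulate = TRUE,
                            input_dir = NULL, keypoints_path = NULL,
                            frames_dir = NULL, groups = NULL,
                            hp = 1, lp = 50, k_sd_channels = 4,
                            k_sd_outliers = 3, pad_ms = 40, skip = 5,
                            ica = FALSE, gamma = 0.1, n_components = NULL,
                            window_len = 1.5, hop = 0.3, k_sum = 3L,
                            theta_low = 2, theta_high = 30,
                            rule_fraction = 0.25,
                            df_method = "satterthwaite", seed = 1L) {
  if (window_len <= hop)
    stop("window_len must exceed hop")
  if (!(theta_low >= 0 && theta_low < theta_high))
    stop("need 0 <= theta_low < theta_high")
  if (!(hp > 0 && hp < lp)) stop("need 0 < hp < lp")
  stopifnot(skip >= 0, pad_ms >= 0, gamma >= 0, gamma <= 1, k_sum >= 1)
  cfg <- list(synth = synth, simulate = simulate, input_dir = input_dir,
              keypoints_path = keypoints_path, frames_dir = frames_dir,
              groups = groups, hp = hp, lp = lp,
              k_sd_channels = k_sd_channels, k_sd_outliers = k_sd_outliers,
              pad_ms = pad_ms, skip = skip, ica = ica, gamma = gamma,
              n_components = n_components, window_len = window_len,
              hop = hop, k_sum = as.integer(k_sum), theta_low = theta_low,
              theta_high = theta_high, rule_fraction = rule_fraction,
              df_method = df_method, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

config_to_json <- function(cfg) {
  x <- unclass(cfg)
  x$synth <- unclass(x$synth)
  x$synth$layout <- as.data.frame(x$synth$layout)
  # named atomic vectors lose their names as JSON arrays; store as objects
  x$synth$movement_gains <- as.list(x$synth$movement_gains)
  x$synth$event_rates <- as.list(x$synth$event_rates)
  if (!is.null(x$groups)) x$groups <- as.list(x$groups)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Read a pipeline config from JSON
#'
#' Round-trips the serialization of [pipeline_config()].
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sy <- x$synth
  synth <- synth_config(
    n_subjects = sy$n_subjects, n_channels = sy$n_channels, fs = sy$fs,
    n_blocks = sy$n_blocks,
    clip_lengths = split(sy$layout$end - sy$layout$start, sy$layout$block),
    mixing = sy$mixing, base_gain = sy$base_gain,
    movement_gains = unlist(sy$movement_gains), noise_sd = sy$noise_sd,
    fps = sy$fps, event_rates = unlist(sy$event_rates),
    artifact_spec = sy$artifact_spec, seed = sy$seed)
  groups <- if (!is.null(x$groups)) unlist(x$groups) else NULL
  pipeline_config(synth = synth, simulate = x$simulate,
                  input_dir = x$input_dir, keypoints_path = x$keypoints_path,
                  frames_dir = x$frames_dir, groups = groups, hp = x$hp,
                  lp = x$lp, k_sd_channels = x$k_sd_channels,
                  k_sd_outliers = x$k_sd_outliers, pad_ms = x$pad_ms,
                  skip = x$skip, ica = x$ica, gamma = x$gamma,
                  n_components = x$n_components, window_len = x$window_len,
                  hop = x$hop, k_sum = x$k_sum, theta_low = x$theta_low,
                  theta_high = x$theta_high, rule_fraction = x$rule_fraction,
                  df_method = x$df_method, seed = x$seed)
}

default_groups <- function(subjects) {
  n <- length(subjects)
  setNames(rep(c("children", "adults"), c(ceiling(n / 2), floor(n / 2))),
           subjects)
}

#' Run the full pipeline
#'
#' Executes the stages in order, writing one delimited table per stage to
#' `out_dir` plus `run_info.json` with the config hash and seed.  A stage
#' failure halts the run with the failing stage named; tables written by
#' earlier stages are retained for inspection.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- config_to_json(cfg)
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  meta <- list(config_hash = cfg_hash, seed = cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  sim <- stage("simulate", {
    if (cfg$simulate) {
      eeg <- generate_eeg(cfg$synth)
      kp <- generate_keypoints(cfg$synth)
      fr <- generate_frames(cfg$synth)
      list(rec = eeg$recording, truth = eeg$truth, track = kp$track,
           stack = fr$stack)
    } else {
      if (is.null(cfg$input_dir)) stop("input_dir required when simulate = FALSE")
      list(rec = read_recording(cfg$input_dir), truth = NULL,
           track = if (!is.null(cfg$keypoints_path))
             read_keypoints(cfg$keypoints_path),
           stack = if (!is.null(cfg$frames_dir)) read_frames(cfg$frames_dir))
    }
  })
  fps <- if (cfg$simulate) cfg$synth$fps else sim$track$fps

  pre <- stage("preprocess", preprocess(
    sim$rec, hp = cfg$hp, lp = cfg$lp, k_sd_channels = cfg$k_sd_channels,
    k_sd_outliers = cfg$k_sd_outliers, pad_ms = cfg$pad_ms,
    skip = cfg$skip, ica = cfg$ica, seed = cfg$seed))
  write_stage_table(data.frame(
    subject = rep(pre$recording$subjects,
                  each = n_channels(pre$recording)),
    channel = rep(pre$recording$channel_labels,
                  n_subjects(pre$recording)),
    zeroed_channel = unlist(lapply(seq_along(pre$report$zeroed_channels),
      function(k) seq_len(n_channels(pre$recording)) %in%
        pre$report$zeroed_channels[[k]])),
    zeroed_fraction = as.numeric(t(pre$report$zeroed_sample_fraction))),
    file.path(out_dir, "preprocess_report.tsv"), meta)

  iscres <- stage("isc", {
    cov <- compute_covariances(pre$recording, pre$excised)
    filters <- fit_corrca(cov, gamma = cfg$gamma,
                          n_components = cfg$n_components)
    isc <- time_resolved_isc(pre$recording, filters,
                             window_len = cfg$window_len, hop = cfg$hop,
                             K = cfg$k_sum, excised = pre$excised)
    list(cov = cov, filters = filters, isc = isc)
  })
  write_stage_table(data.frame(component = seq_along(iscres$filters$rho),
                               rho = iscres$filters$rho),
                    file.path(out_dir, "corrca_rho.tsv"), meta)
  write_stage_table(as.data.frame(iscres$filters$W),
                    file.path(out_dir, "corrca_W.tsv"), meta)
  write_stage_table(as.data.frame(iscres$filters$A),
                    file.path(out_dir, "corrca_A.tsv"), meta)
  wtab <- iscres$isc$grid[iscres$isc$grid$retained, c("window", "start")]
  wide <- cbind(wtab, as.data.frame(t(iscres$isc$windows)))
  write_stage_table(wide, file.path(out_dir, "isc_windows.tsv"), meta)
  write_stage_table(data.frame(subject = names(iscres$isc$global),
                               isc = unname(iscres$isc$global)),
                    file.path(out_dir, "isc_global.tsv"), meta)

  spans <- mask_to_spans(pre$excised, pre$recording$fs)
  moves <- stage("annotate", {
    if (is.null(sim$track)) stop("no keypoint input available")
    d <- limb_displacement(sim$track)
    flags <- classify_frames(d, cfg$theta_low, cfg$theta_high)
    window_categories(flags, iscres$isc$grid, fps, spans,
                      cfg$rule_fraction,
                      theta = c(cfg$theta_low, cfg$theta_high))
  })
  write_stage_table(as.data.frame(moves),
                    file.path(out_dir, "movement.tsv"), meta)

  ald <- stage("ald", {
    if (is.null(sim$stack)) stop("no frame input available")
    downsample_ald(stack_ald(sim$stack), iscres$isc$grid, fps, spans,
                   layout = sim$rec$layout)
  })
  write_stage_table(as.data.frame(ald), file.path(out_dir, "ald.tsv"), meta)

  modelres <- stage("model", {
    groups <- if (!is.null(cfg$groups)) cfg$groups else
      default_groups(sim$rec$subjects)
    design <- build_design(iscres$isc, moves, ald, groups,
                           layout = sim$rec$layout)
    fit <- fit_engagement_model(design, df_method = cfg$df_method)
    post <- posthoc_wilcoxon(design)
    list(design = design, fit = fit, posthoc = post)
  })
  write_stage_table(as.data.frame(modelres$design),
                    file.path(out_dir, "design.tsv"), meta)
  write_stage_table(modelres$fit$coefficients,
                    file.path(out_dir, "model_fit.tsv"), meta)
  write_stage_table(modelres$posthoc$comparisons,
                    file.path(out_dir, "posthoc.tsv"), meta)

  stage("report", {
    con <- file(file.path(out_dir, "report.txt"), open = "wt")
    sink(con); on.exit({ sink(); close(con) })
    cat("Run", cfg_hash, "seed", cfg$seed, "\n\n")
    print(modelres$fit)
    cat("\nPer-condition mean ISC (per-subject means averaged):\n")
    cm <- stats::aggregate(isc ~ group + movement,
                           data = modelres$posthoc$cells, FUN = mean)
    print(cm, digits = 4)
    cat("\n")
    print(modelres$posthoc)
  })
  jsonlite::write_json(meta, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE)
  invisible(list(out_dir = out_dir, recording = pre$recording,
                 excised = pre$excised, filters = iscres$filters,
                 isc = iscres$isc, movement = moves, ald = ald,
                 design = modelres$design, fit = modelres$fit,
                 posthoc = modelres$posthoc, truth = sim$truth))
}
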