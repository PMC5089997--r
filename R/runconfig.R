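#' Read and write pipeline run configurations (YAML)
#'
#' A run configuration bundles the generator block ([sim_config()]
#' arguments under `sim`, with per-condition parameters under
#' `sim$conditions` as a list of rows), the analysis thresholds
#' ([analysis_params()] names under `analysis`), the reading-velocity
#' generator block under `velocity`, and `out_dir`.  Writing and
#' re-reading a configuration is an identity.
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a list with elements `sim` (an
#'   `evs_sim_config`), `analysis`, `velocity` and `out_dir`;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  if (!is.null(sim_args$conditions)) {
    sim_args$conditions <- do.call(rbind, lapply(sim_args$conditions,
                                                 as.data.frame))
  }
  cfg <- do.call(sim_config, if (is.null(sim_args)) list() else sim_args)
  params <- do.call(analysis_params,
                    if (is.null(y$analysis)) list() else y$analysis)
  velocity <- list(slope = 0.05, intercept = 30, noise_sd = 5,
                   max_score = 75)
  if (!is.null(y$velocity)) velocity[names(y$velocity)] <- y$velocity
  list(sim = cfg, analysis = params, velocity = velocity,
       out_dir = y$out_dir)
}

#' @rdname read_run_config
#' @param run_config List as returned by `read_run_config` (or assembled
#'   manually from a `sim` config plus parameter lists).
#' @export
write_run_config <- function(run_config, path) {
  cfg <- run_config$sim
  sim <- list(
    seed = cfg$seed, sampling_rate_hz = cfg$sampling_rate_hz,
    n_subjects = cfg$n_subjects, mode = cfg$mode,
    conditions = lapply(seq_len(nrow(cfg$conditions)), function(i)
      as.list(cfg$conditions[i, ])),
    subject_var = cfg$subject_var, item_var = cfg$item_var,
    blink_rate = cfg$rates$blink, skip_rate = cfg$rates$skip,
    regression_rate = cfg$rates$regression,
    misarticulation_rate = cfg$rates$misarticulation,
    accidental_entry_rate = cfg$rates$accidental_entry,
    signal_loss_rate = cfg$rates$signal_loss,
    signal_loss_fraction = cfg$signal_loss_fraction,
    blink_ms = cfg$blink_ms,
    regression_fixation_ms = cfg$regression_fixation_ms,
    accidental_fixation_ms = cfg$accidental_fixation_ms,
    saccade_peak_velocity = cfg$saccade_peak_velocity,
    saccade_floor_velocity = cfg$saccade_floor_velocity,
    fixation_jitter_sd = cfg$fixation_jitter_sd,
    start_fixation_ms = cfg$start_fixation_ms,
    end_fixation_ms = cfg$end_fixation_ms,
    min_gaze_ms = cfg$min_gaze_ms,
    aoi_width = cfg$geometry$aoi_width,
    aoi_height = cfg$geometry$aoi_height,
    min_spacing = cfg$geometry$min_spacing,
    row_gap = cfg$geometry$row_gap,
    origin_x = cfg$geometry$origin_x, origin_y = cfg$geometry$origin_y,
    rows_short = cfg$grid$rows_short, cols_short = cfg$grid$cols_short,
    rows_long = cfg$grid$rows_long, cols_long = cfg$grid$cols_long,
    items_per_cell = cfg$items_per_cell,
    regular_per_cell = cfg$regular_per_cell,
    filler_policy = cfg$filler_policy,
    voice_sync_offset_ms = cfg$voice_sync_offset_ms,
    calibrate_truncation = cfg$calibrate_truncation,
    max_resample = cfg$max_resample)
  yaml::write_yaml(list(sim = sim, analysis = run_config$analysis,
                        velocity = run_config$velocity,
                        out_dir = run_config$out_dir), path)
  invisible(path)
}
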