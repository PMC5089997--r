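#' Simulation configuration for the synthetic gaze/voice generator
#'
#' Builds the full generative parameterization used by
#' [build_stimulus_lists()], [simulate_trial()] and [simulate_experiment()].
#' Defaults reproduce the study design the package emulates: 1250 Hz
#' monocular gaze sampling, 3x4 (long items) / 3x5 (short items) grid lists
#' with at least 6.8 degrees of horizontal spacing between areas of
#' interest, 40 experimental items per familiarity x length cell
#' (30 regular + 10 irregular), and per-condition offset-EVS and GT/PT
#' distributions matching the reported condition means and standard
#' deviations.
#'
#' Two sampling modes are available per item:
#' \describe{
#'   \item{`"offset"`}{first-pass gaze time G and offset EVS E are drawn
#'     from independent per-condition normals; onset EVS is G + E.}
#'   \item{`"ratio"`}{processing time P (onset EVS) and the GT/PT ratio R
#'     are drawn from per-condition normals; then G = R*P and E = P*(1-R).}
#' }
#' Draws implying a non-positive onset EVS (or a first-pass gaze shorter
#' than `min_gaze_ms`) are rejected and resampled.  Because rejection
#' truncates the marginals, the sampler by default moment-matches the
#' latent normal parameters so that the distribution *after* rejection has
#' the configured mean and SD (`calibrate_truncation = TRUE`).
#'
#' @param seed Integer seed stored with the configuration; `simulate_*`
#'   entry points call `set.seed()` with it when non-`NULL`.
#' @param sampling_rate_hz Gaze sampling rate in Hz.
#' @param n_subjects Number of simulated subjects.
#' @param mode `"offset"` or `"ratio"` (see Details).
#' @param conditions Data frame of per-condition generative parameters,
#'   one row per familiarity x length cell, with columns `familiarity`
#'   (`"HF"`, `"LF"`, `"PW"`), `length_class` (`"short"`, `"long"`),
#'   `offset_mean`, `offset_sd`, `gaze_mean`, `gaze_sd` (ms, offset mode),
#'   `gtpt_mean`, `gtpt_sd` (dimensionless) and `pt_mean`, `pt_sd`
#'   (ms, ratio mode).  Defaults via [default_conditions()].
#' @param subject_var,item_var Variance (ms^2) of subject and item random
#'   intercepts added to each item's offset EVS in stream simulation.
#'   Default 0: the per-condition SDs above are marginal SDs and already
#'   contain subject/item variance; nonzero components are for explicitly
#'   crossed-design simulations.
#' @param blink_rate,skip_rate,regression_rate,misarticulation_rate
#'   Per-item artifact probabilities.
#' @param accidental_entry_rate,signal_loss_rate Per-trial artifact
#'   probabilities.
#' @param signal_loss_fraction Fraction of trial samples invalidated when
#'   a signal-loss artifact is injected.
#' @param blink_ms,regression_fixation_ms,accidental_fixation_ms Durations
#'   (ms) of injected blink, second-pass fixation and accidental-entry
#'   fixation.
#' @param saccade_peak_velocity,saccade_floor_velocity Peak and floor of
#'   the synthesized saccade velocity profile (deg/s).  The floor keeps the
#'   whole movement above the I-VT detection threshold so that event
#'   boundaries are recoverable to within a sample.
#' @param fixation_jitter_sd Per-sample positional jitter SD (deg) during
#'   fixations.
#' @param start_fixation_ms,end_fixation_ms Duration of the neutral
#'   fixations opening and closing each trial.
#' @param min_gaze_ms Lower bound enforced on generated first-pass gaze
#'   times (a gaze below the minimum-fixation criterion could not survive
#'   detection).
#' @param aoi_width,aoi_height AOI rectangle size in degrees.
#' @param min_spacing Minimum horizontal gap between adjacent AOIs
#'   (degrees).
#' @param row_gap Vertical gap between AOI rows (degrees).
#' @param origin_x,origin_y Top-left corner of the first AOI (degrees).
#' @param rows_short,cols_short,rows_long,cols_long List grid geometry.
#' @param items_per_cell,regular_per_cell Experimental items per
#'   familiarity x length cell and how many of them are regular (the
#'   remainder is irregular).
#' @param filler_policy `"pad"` (default) turns leftover experimental
#'   slots of the last list of a cell into fillers; `"strict"` raises an
#'   error naming the cell when items do not partition exactly.
#' @param voice_sync_offset_ms Constant added to all voice-onset times,
#'   modelling recorder desynchronization (0 = perfect sync).
#' @param calibrate_truncation Moment-match latent sampling parameters for
#'   the rejection step (see Details).
#' @param max_resample Cap on rejection-sampling attempts per item.
#'
#' @return An object of class `evs_sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_subjects = 2)
#' cfg$conditions
#' @export
sim_config <- function(seed = NULL,
                       sampling_rate_hz = 1250,
                       n_subjects = 36,
                       mode = c("offset", "ratio"),
                       conditions = default_conditions(),
                       subject_var = 0,
                       item_var = 0,
                       blink_rate = 0.05,
                       skip_rate = 0.05,
                       regression_rate = 0.10,
                       misarticulation_rate = 0.03,
                       accidental_entry_rate = 0.02,
                       signal_loss_rate = 0.05,
                       signal_loss_fraction = 0.30,
                       blink_ms = 120,
                       regression_fixation_ms = 150,
                       accidental_fixation_ms = 100,
                       saccade_peak_velocity = 200,
                       saccade_floor_velocity = 60,
                       fixation_jitter_sd = 0.01,
                       start_fixation_ms = 300,
                       end_fixation_ms = 100,
                       min_gaze_ms = 50,
                       aoi_width = 4,
                       aoi_height = 2,
                       min_spacing = 6.8,
                       row_gap = 2.5,
                       origin_x = 2,
                       origin_y = 2,
                       rows_short = 3, cols_short = 5,
                       rows_long = 3, cols_long = 4,
                       items_per_cell = 40,
                       regular_per_cell = 30,
                       filler_policy = c("pad", "strict"),
                       voice_sync_offset_ms = 0,
                       calibrate_truncation = TRUE,
                       max_resample = 1000) {
  mode <- match.arg(mode)
  filler_policy <- match.arg(filler_policy)
  stopifnot(is.data.frame(conditions))
  needed <- c("familiarity", "length_class", "offset_mean", "offset_sd",
              "gaze_mean", "gaze_sd", "gtpt_mean", "gtpt_sd",
              "pt_mean", "pt_sd")
  missing_cols <- setdiff(needed, names(conditions))
  if (length(missing_cols)) {
    stop("conditions is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be > 0")
  sds <- unlist(conditions[c("offset_sd", "gaze_sd", "gtpt_sd", "pt_sd")])
  if (any(sds < 0)) stop("all condition SDs must be >= 0")
  if (subject_var < 0 || item_var < 0) stop("variance components must be >= 0")
  rates <- c(blink = blink_rate, skip = skip_rate, regression = regression_rate,
             misarticulation = misarticulation_rate,
             accidental_entry = accidental_entry_rate,
             signal_loss = signal_loss_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("artifact rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  }
  if (items_per_cell < 0 || regular_per_cell < 0 ||
      regular_per_cell > items_per_cell) {
    stop("regular_per_cell must lie in [0, items_per_cell]")
  }
  cfg <- list(
    seed = seed, sampling_rate_hz = sampling_rate_hz,
    dt_ms = 1000 / sampling_rate_hz,
    n_subjects = n_subjects, mode = mode, conditions = conditions,
    subject_var = subject_var, item_var = item_var,
    rates = as.list(rates),
    signal_loss_fraction = signal_loss_fraction,
    blink_ms = blink_ms,
    regression_fixation_ms = regression_fixation_ms,
    accidental_fixation_ms = accidental_fixation_ms,
    saccade_peak_velocity = saccade_peak_velocity,
    saccade_floor_velocity = saccade_floor_velocity,
    fixation_jitter_sd = fixation_jitter_sd,
    start_fixation_ms = start_fixation_ms,
    end_fixation_ms = end_fixation_ms,
    min_gaze_ms = min_gaze_ms,
    geometry = list(aoi_width = aoi_width, aoi_height = aoi_height,
                    min_spacing = min_spacing, row_gap = row_gap,
                    origin_x = origin_x, origin_y = origin_y),
    grid = list(rows_short = rows_short, cols_short = cols_short,
                rows_long = rows_long, cols_long = cols_long),
    items_per_cell = items_per_cell,
    regular_per_cell = regular_per_cell,
    filler_policy = filler_policy,
    voice_sync_offset_ms = voice_sync_offset_ms,
    calibrate_truncation = calibrate_truncation,
    max_resample = max_resample
  )
  class(cfg) <- "evs_sim_config"
  cfg
}

#' Default per-condition generative parameters
#'
#' Offset-EVS and GT/PT means and SDs are the reported condition values of
#' the emulated study.  Per-condition first-pass gaze means are not
#' reported there; they are derived from the identity
#' gaze = offset * R / (1 - R) (R the GT/PT mean), whose grand mean
#' (~497 ms) is consistent with the reported overall gaze time of 494 ms.
#' Processing-time (onset EVS) means follow as pt = gaze / R.  Gaze and
#' processing-time SDs are unreported; 120 ms and 150 ms are adopted as
#' realistic values for oral reading.
#'
#' @return Data frame with one row per familiarity x length condition.
#' @export
default_conditions <- function() {
  cells <- data.frame(
    familiarity  = rep(c("HF", "LF", "PW"), each = 2),
    length_class = rep(c("short", "long"), 3),
    offset_mean  = c(258.9, 191.4, 210.2, 80.9, 122.7, -63.1),
    offset_sd    = c(134.8, 155.9, 151.7, 173.8, 169.2, 185.0),
    gtpt_mean    = c(0.59, 0.71, 0.68, 0.89, 0.82, 1.15),
    gtpt_sd      = c(0.18, 0.23, 0.22, 0.28, 0.27, 0.36),
    stringsAsFactors = FALSE
  )
  cells$gaze_mean <- cells$offset_mean * cells$gtpt_mean / (1 - cells$gtpt_mean)
  cells$gaze_sd <- 120
  cells$pt_mean <- cells$gaze_mean / cells$gtpt_mean
  cells$pt_sd <- 150
  cells
}

#' @export
print.evs_sim_config <- function(x, ...) {
  cat("Eye-voice span simulation configuration\n")
  cat(sprintf("  mode: %s | sampling: %g Hz | subjects: %d | seed: %s\n",
              x$mode, x$sampling_rate_hz, x$n_subjects,
              if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  variance components (ms^2): subject %g, item %g\n",
              x$subject_var, x$item_var))
  cat(sprintf("  artifact rates: %s\n",
              paste(sprintf("%s %.2f", names(x$rates), unlist(x$rates)),
                    collapse = ", ")))
  cat(sprintf("  grid: long %dx%d, short %dx%d, %d items/cell, spacing %.1f deg\n",
              x$grid$rows_long, x$grid$cols_long,
              x$grid$rows_short, x$grid$cols_short,
              x$items_per_cell, x$geometry$min_spacing))
  invisible(x)
}

condition_key <- function(familiarity, length_class) {
  paste(familiarity, length_class, sep = "_")
}

lookup_condition <- function(config, familiarity, length_class) {
  cond <- config$conditions
  hit <- cond$familiarity == familiarity & cond$length_class == length_class
  if (!any(hit)) {
    stop("unknown condition: ", condition_key(familiarity, length_class))
  }
  cond[which(hit)[1L], , drop = FALSE]
}
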