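#' Per-sample angular gaze velocity
#'
#' Central-difference velocity over a symmetric window, in degrees per
#' second.  Velocity is computed independently within each run of valid
#' samples (windows never straddle invalid samples, whose coordinates are
#' meaningless); edge samples of a run take the nearest interior estimate,
#' and runs too short for the window get velocity 0.  Invalid samples are
#' marked `NA`.
#'
#' @param track Gaze track data frame with columns `time_ms`, `x_deg`,
#'   `y_deg`, `valid` (0/1).
#' @param window Window size in samples (odd; default 5, i.e. +/-2 samples
#'   = 4 ms at 1250 Hz).
#' @return Numeric vector of velocities (deg/s), one per sample.
#' @examples
#' tr <- data.frame(time_ms = 0:99 * 0.8, x_deg = 1, y_deg = 1, valid = 1)
#' range(compute_velocity(tr))
#' @export
compute_velocity <- function(track, window = 5) {
  n <- nrow(track)
  if (n <= window) stop("track shorter than the velocity window")
  h <- floor(window / 2)
  v <- rep(NA_real_, n)
  valid <- track$valid != 0
  runs <- run_bounds(valid)
  for (k in seq_len(nrow(runs))) {
    if (!runs$value[k]) next
    i0 <- runs$start[k]; i1 <- runs$end[k]
    m <- i1 - i0 + 1L
    if (m <= 2L * h) { v[i0:i1] <- 0; next }
    idx <- (i0 + h):(i1 - h)
    dx <- track$x_deg[idx + h] - track$x_deg[idx - h]
    dy <- track$y_deg[idx + h] - track$y_deg[idx - h]
    dtm <- track$time_ms[idx + h] - track$time_ms[idx - h]
    vv <- sqrt(dx^2 + dy^2) / (dtm / 1000)
    v[idx] <- vv
    v[i0:(i0 + h - 1L)] <- vv[1L]
    v[(i1 - h + 1L):i1] <- vv[length(vv)]
  }
  v
}

# start/end/value of maximal runs of a logical (or atomic) vector
run_bounds <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end, value = r$values)
}

#' I-VT event detection
#'
#' Segments a gaze track into saccades, fixations, blinks, signal-loss
#' intervals and discarded (sub-minimum) fixations.  Within each run of
#' valid samples, maximal runs with velocity strictly above
#' `velocity_threshold` become saccades and the complementary runs become
#' fixations; fixations shorter than `min_fixation_ms` are re-labelled
#' `discarded` (rejected, not merged).  Runs of invalid samples become
#' `blink` when they last at most `blink_max_ms` and are bracketed by
#' valid data, otherwise `lost`.  Events are half-open `[t_start, t_end)`
#' intervals on the sample grid and exactly partition the track duration.
#'
#' @param track Gaze track data frame (`time_ms`, `x_deg`, `y_deg`,
#'   `valid`), timestamps strictly increasing on a uniform grid.
#' @param velocity_threshold Saccade threshold in deg/s (default 30).
#' @param min_fixation_ms Minimum fixation duration in ms (default 50).
#' @param blink_max_ms Longest invalid run still classified as a blink.
#' @param velocity_window Passed to [compute_velocity()].
#' @param trial_id Identifier copied into the output.
#' @return Data frame of ordered events: `trial_id`, `kind`,
#'   `t_start_ms`, `t_end_ms`, `x`, `y` (fixation centroid),
#'   `peak_velocity` (saccades).  An all-invalid track yields a single
#'   `lost` event carrying attribute `all_lost = TRUE`.
#' @examples
#' tr <- data.frame(time_ms = 0:199 * 0.8, x_deg = 1, y_deg = 1, valid = 1)
#' detect_events(tr)[, c("kind", "t_start_ms", "t_end_ms")]
#' @export
detect_events <- function(track, velocity_threshold = 30,
                          min_fixation_ms = 50, blink_max_ms = 500,
                          velocity_window = 5, trial_id = "T01") {
  n <- nrow(track)
  if (n == 0L) stop("empty track")
  if (velocity_threshold <= 0 || min_fixation_ms <= 0) {
    stop("thresholds must be positive")
  }
  tm <- track$time_ms
  if (n > 1L && any(diff(tm) <= 0)) stop("timestamps must be strictly increasing")
  dt <- if (n > 1L) stats::median(diff(tm)) else 1
  end_time <- tm[n] + dt
  t_of <- function(i0, i1) {  # half-open [t[i0], t[i1] + dt)
    c(tm[i0], if (i1 < n) tm[i1 + 1L] else end_time)
  }
  valid <- track$valid != 0
  if (!any(valid)) {
    ev <- data.frame(trial_id = trial_id, kind = "lost",
                     t_start_ms = tm[1], t_end_ms = end_time,
                     x = NA_real_, y = NA_real_, peak_velocity = NA_real_,
                     stringsAsFactors = FALSE)
    attr(ev, "all_lost") <- TRUE
    return(ev)
  }
  v <- compute_velocity(track, velocity_window)
  runs <- run_bounds(valid)
  out <- list()
  for (k in seq_len(nrow(runs))) {
    i0 <- runs$start[k]; i1 <- runs$end[k]
    tt <- t_of(i0, i1)
    if (!runs$value[k]) {
      dur <- tt[2] - tt[1]
      bracketed <- i0 > 1L && i1 < n
      kind <- if (bracketed && dur <= blink_max_ms) "blink" else "lost"
      out[[length(out) + 1L]] <- data.frame(
        trial_id = trial_id, kind = kind, t_start_ms = tt[1],
        t_end_ms = tt[2], x = NA_real_, y = NA_real_,
        peak_velocity = NA_real_, stringsAsFactors = FALSE)
      next
    }
    sac <- v[i0:i1] > velocity_threshold
    sub <- run_bounds(sac)
    for (j in seq_len(nrow(sub))) {
      j0 <- i0 + sub$start[j] - 1L
      j1 <- i0 + sub$end[j] - 1L
      st <- t_of(j0, j1)
      if (sub$value[j]) {
        out[[length(out) + 1L]] <- data.frame(
          trial_id = trial_id, kind = "saccade", t_start_ms = st[1],
          t_end_ms = st[2], x = NA_real_, y = NA_real_,
          peak_velocity = max(v[j0:j1]), stringsAsFactors = FALSE)
      } else {
        dur <- st[2] - st[1]
        kind <- if (dur < min_fixation_ms) "discarded" else "fixation"
        out[[length(out) + 1L]] <- data.frame(
          trial_id = trial_id, kind = kind, t_start_ms = st[1],
          t_end_ms = st[2], x = mean(track$x_deg[j0:j1]),
          y = mean(track$y_deg[j0:j1]), peak_velocity = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$t_start_ms), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Per-trial signal-loss statistics
#'
#' @param trials A list of `evs_trial` objects (or of gaze-track data
#'   frames with `subject_id`/`trial_id` attributes supplied via names).
#' @return Data frame `subject_id`, `trial_id`, `n_samples`, `n_invalid`,
#'   `invalid_frac`.
#' @export
contamination_stats <- function(trials) {
  rows <- lapply(trials, function(tr) {
    if (inherits(tr, "evs_trial")) {
      track <- tr$track
      data.frame(subject_id = tr$subject_id, trial_id = tr$trial_id,
                 n_samples = nrow(track),
                 n_invalid = sum(track$valid == 0),
                 stringsAsFactors = FALSE)
    } else {
      stop("contamination_stats expects evs_trial objects")
    }
  })
  out <- do.call(rbind, rows)
  out$invalid_frac <- out$n_invalid / out$n_samples
  rownames(out) <- NULL
  out
}

#' Contamination flags for trials and subjects
#'
#' A trial is contaminated when its invalid-sample fraction strictly
#' exceeds `trial_threshold`; a subject is excluded when the fraction of
#' their contaminated trials strictly exceeds `subject_threshold`.
#'
#' @param trial_stats Data frame as returned by [contamination_stats()]
#'   (or any frame with `subject_id`, `trial_id` and `invalid_frac`).
#' @param trial_threshold,subject_threshold Strict-inequality cutoffs
#'   (defaults 0.25).
#' @return Object of class `evs_contamination`: list with data frames
#'   `trials` (`..., contaminated`) and `subjects`
#'   (`subject_id`, `n_trials`, `n_contaminated`, `contaminated_frac`,
#'   `excluded`).
#' @examples
#' st <- data.frame(subject_id = "S01", trial_id = c("L1", "L2"),
#'                  invalid_frac = c(0.30, 0.10))
#' flag_contamination(st)$trials$contaminated
#' @export
flag_contamination <- function(trial_stats, trial_threshold = 0.25,
                               subject_threshold = 0.25) {
  stopifnot(all(c("subject_id", "trial_id", "invalid_frac") %in%
                  names(trial_stats)))
  trials <- trial_stats
  trials$contaminated <- trials$invalid_frac > trial_threshold
  agg <- stats::aggregate(contaminated ~ subject_id, data = trials,
                          FUN = function(z) c(n = length(z), k = sum(z)))
  subjects <- data.frame(subject_id = agg$subject_id,
                         n_trials = agg$contaminated[, "n"],
                         n_contaminated = agg$contaminated[, "k"],
                         stringsAsFactors = FALSE)
  subjects$contaminated_frac <- subjects$n_contaminated / subjects$n_trials
  subjects$excluded <- subjects$contaminated_frac > subject_threshold
  structure(list(trials = trials, subjects = subjects,
                 trial_threshold = trial_threshold,
                 subject_threshold = subject_threshold),
            class = "evs_contamination")
}

#' @export
print.evs_contamination <- function(x, ...) {
  cat(sprintf(
    "Contamination report: %d/%d trials contaminated (> %.0f%% loss), %d/%d subjects excluded (> %.0f%% contaminated trials)\n",
    sum(x$trials$contaminated), nrow(x$trials), 100 * x$trial_threshold,
    sum(x$subjects$excluded), nrow(x$subjects), 100 * x$subject_threshold))
  invisible(x)
}
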