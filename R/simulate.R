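## ---------------------------------------------------------------------------
## Truncation-aware sampling of per-item timing
## ---------------------------------------------------------------------------

# Moments of an independent normal pair (O, I) conditional on the
# acceptance region {O >= lower_o, I >= cutoff(O)}.  The inner moments are
# closed-form truncated-normal expressions; the outer integral is smooth
# and handled by stats::integrate.  Used to moment-match the rejection
# sampler so the retained marginals carry the configured mean/SD.
truncated_pair_moments <- function(muO, sO, muI, sI, lower_o, cutoff) {
  inner <- function(o, pow) {  # E[I^pow ; I >= cutoff(o)] for pow in 0:2
    cc <- cutoff(o)
    if (sI == 0) {
      keep <- as.numeric(muI >= cc)
      return(keep * muI^pow)
    }
    z <- (cc - muI) / sI
    surv <- stats::pnorm(z, lower.tail = FALSE)
    phi <- stats::dnorm(z)
    switch(as.character(pow),
           "0" = surv,
           "1" = muI * surv + sI * phi,
           "2" = (muI^2 + sI^2) * surv + sI * (muI + cc) * phi)
  }
  if (sO == 0) {
    if (muO < lower_o) stop("degenerate outer variable below its bound")
    Z <- inner(muO, 0)
    if (Z <= 0) stop("acceptance probability is zero")
    mI <- inner(muO, 1) / Z
    vI <- inner(muO, 2) / Z - mI^2
    return(list(Z = Z, mO = muO, sdO = 0, mI = mI, sdI = sqrt(max(vI, 0))))
  }
  lo <- max(lower_o, muO - 10 * sO)
  hi <- muO + 10 * sO
  ig <- function(f) {
    stats::integrate(function(o) stats::dnorm(o, muO, sO) * f(o), lo, hi,
                     rel.tol = 1e-9, subdivisions = 400L)$value
  }
  Z <- ig(function(o) inner(o, 0))
  if (Z <= 0) stop("acceptance probability is zero")
  mO <- ig(function(o) o * inner(o, 0)) / Z
  vO <- ig(function(o) o^2 * inner(o, 0)) / Z - mO^2
  mI <- ig(function(o) inner(o, 1)) / Z
  vI <- ig(function(o) inner(o, 2)) / Z - mI^2
  list(Z = Z, mO = mO, sdO = sqrt(max(vO, 0)), mI = mI,
       sdI = sqrt(max(vI, 0)))
}

# Fixed-point moment matching: find latent (muO, sO, muI, sI) whose
# post-rejection moments equal the targets.
calibrate_pair <- function(tO, tsO, tI, tsI, lower_o, cutoff,
                           iterations = 25) {
  muO <- tO; sO <- tsO; muI <- tI; sI <- tsI
  for (k in seq_len(iterations)) {
    m <- truncated_pair_moments(muO, sO, muI, sI, lower_o, cutoff)
    muO <- muO + (tO - m$mO)
    muI <- muI + (tI - m$mI)
    if (tsO > 0 && m$sdO > 0) sO <- sO * tsO / m$sdO
    if (tsI > 0 && m$sdI > 0) sI <- sI * tsI / m$sdI
    if (abs(tO - m$mO) < 1e-6 && abs(tI - m$mI) < 1e-6 &&
        abs(tsO - m$sdO) < 1e-6 && abs(tsI - m$sdI) < 1e-6) break
  }
  list(muO = muO, sO = sO, muI = muI, sI = sI)
}

.calib_cache <- new.env(parent = emptyenv())

memo_calibrate <- function(key, fn) {
  if (!exists(key, envir = .calib_cache)) {
    assign(key, fn(), envir = .calib_cache)
  }
  get(key, envir = .calib_cache)
}

# Offset mode: outer = gaze time G (>= min_gaze), inner = offset EVS E
# with acceptance E > -G (positive onset EVS).
calibrate_offset_params <- function(gaze_mean, gaze_sd, offset_mean, offset_sd,
                                    min_gaze) {
  key <- paste("off", gaze_mean, gaze_sd, offset_mean, offset_sd, min_gaze)
  memo_calibrate(key, function() {
    cal <- calibrate_pair(gaze_mean, gaze_sd, offset_mean, offset_sd,
                          lower_o = min_gaze, cutoff = function(o) -o)
    list(muG = cal$muO, sG = cal$sO, muE = cal$muI, sE = cal$sI)
  })
}

# Ratio mode: outer = processing time P (> 0), inner = ratio R with
# acceptance R*P >= min_gaze.
calibrate_ratio_params <- function(pt_mean, pt_sd, gtpt_mean, gtpt_sd,
                                   min_gaze) {
  key <- paste("rat", pt_mean, pt_sd, gtpt_mean, gtpt_sd, min_gaze)
  memo_calibrate(key, function() {
    cal <- calibrate_pair(pt_mean, pt_sd, gtpt_mean, gtpt_sd,
                          lower_o = 1e-9, cutoff = function(o) min_gaze / o)
    list(muP = cal$muO, sP = cal$sO, muR = cal$muI, sR = cal$sI)
  })
}

#' Draw per-item gaze time and offset EVS for one condition
#'
#' Samples item-level timing according to the configured mode.  In offset
#' mode, first-pass gaze time G and offset EVS E come from independent
#' per-condition normals; in ratio mode, processing time P (onset EVS) and
#' the GT/PT ratio R are drawn and G = R*P, E = P*(1-R).  Draws with a
#' non-positive onset EVS (G + E <= 0) or with G below `min_gaze_ms` are
#' rejected and resampled; with `calibrate_truncation = TRUE` (default)
#' the latent parameters are moment-matched so the retained distribution
#' has the configured mean and SD.
#'
#' @param familiarity,length_class Condition labels present in
#'   `config$conditions`.
#' @param config An [sim_config()] object.
#' @param n Number of items to draw.
#' @param shift Additive shift (ms) applied to each item's offset EVS
#'   (used for subject/item random intercepts).
#' @return Data frame with columns `gaze_ms`, `offset_evs_ms`,
#'   `onset_evs_ms`, `gt_pt`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' set.seed(1)
#' simulate_item_timing("HF", "short", cfg, n = 3)
#' @export
simulate_item_timing <- function(familiarity, length_class, config, n = 1,
                                 shift = 0) {
  cond <- lookup_condition(config, familiarity, length_class)
  if (n == 0) {
    return(data.frame(gaze_ms = numeric(), offset_evs_ms = numeric(),
                      onset_evs_ms = numeric(), gt_pt = numeric()))
  }
  min_gaze <- config$min_gaze_ms
  if (config$mode == "offset") {
    if (config$calibrate_truncation) {
      lat <- calibrate_offset_params(cond$gaze_mean, cond$gaze_sd,
                                     cond$offset_mean, cond$offset_sd,
                                     min_gaze)
    } else {
      lat <- list(muG = cond$gaze_mean, sG = cond$gaze_sd,
                  muE = cond$offset_mean, sE = cond$offset_sd)
    }
    G <- numeric(0); E <- numeric(0)
    attempts <- 0
    while (length(G) < n) {
      attempts <- attempts + 1
      if (attempts > config$max_resample) {
        stop("exceeded max_resample attempts for condition ",
             condition_key(familiarity, length_class))
      }
      m <- n - length(G)
      g <- stats::rnorm(m, lat$muG, lat$sG)
      e <- stats::rnorm(m, lat$muE + shift, lat$sE)
      ok <- (g + e) > 0 & g >= min_gaze
      G <- c(G, g[ok]); E <- c(E, e[ok])
    }
    data.frame(gaze_ms = G, offset_evs_ms = E, onset_evs_ms = G + E,
               gt_pt = G / (G + E))
  } else {
    if (config$calibrate_truncation) {
      lat <- calibrate_ratio_params(cond$pt_mean, cond$pt_sd,
                                    cond$gtpt_mean, cond$gtpt_sd, min_gaze)
    } else {
      lat <- list(muP = cond$pt_mean, sP = cond$pt_sd,
                  muR = cond$gtpt_mean, sR = cond$gtpt_sd)
    }
    P <- numeric(0); R <- numeric(0)
    attempts <- 0
    while (length(P) < n) {
      attempts <- attempts + 1
      if (attempts > config$max_resample) {
        stop("exceeded max_resample attempts for condition ",
             condition_key(familiarity, length_class))
      }
      m <- n - length(P)
      p <- stats::rnorm(m, lat$muP, lat$sP)
      r <- stats::rnorm(m, lat$muR, lat$sR)
      g <- r * p
      ok <- p > 0 & g >= min_gaze & (p + shift) > 0
      P <- c(P, p[ok]); R <- c(R, r[ok])
    }
    G <- R * P
    E <- P - G + shift
    data.frame(gaze_ms = G, offset_evs_ms = E, onset_evs_ms = G + E,
               gt_pt = G / (G + E))
  }
}

## ---------------------------------------------------------------------------
## Scanpath synthesis
## ---------------------------------------------------------------------------

# Saccade sample positions between two points.  The speed profile is a
# minimum-jerk-like bump riding on a floor velocity: v(tau) = v0 +
# (vp - v0) * 16 tau^2 (1-tau)^2, so the whole movement stays above the
# I-VT threshold and detected boundaries are sample-accurate.
saccade_samples <- function(from, to, config) {
  A <- sqrt(sum((to - from)^2))
  if (A < 1e-9) return(matrix(numeric(0), ncol = 2))
  v0 <- config$saccade_floor_velocity
  vp <- max(config$saccade_peak_velocity, v0)
  mean_v <- v0 + (16 / 30) * (vp - v0)
  T_ms <- A / mean_v * 1000
  n <- max(2L, as.integer(round(T_ms / config$dt_ms)))
  tau <- (seq_len(n) - 0.5) / n
  v <- v0 + (vp - v0) * 16 * tau^2 * (1 - tau)^2
  f <- cumsum(v) / sum(v)
  cbind(from[1] + f * (to[1] - from[1]),
        from[2] + f * (to[2] - from[2]))
}

#' Simulate one list-reading trial
#'
#' Produces the raw gaze sample stream, the voice-onset annotations and
#' the generative ground truth for a single presentation of one stimulus
#' list.  The scanpath starts on a neutral position left of the grid,
#' visits every AOI in reading order (row-major), and ends on a neutral
#' position below the grid.  Each visited AOI receives a run of fixation
#' samples realizing its drawn first-pass gaze time (quantized to the
#' sample grid; ground truth records the realized value), and the voice
#' onset of item N is placed at first-entry(N) + gaze(N) + offset-EVS(N).
#'
#' Artifacts are injected according to the configured rates and recorded
#' as ground-truth labels: blinks (invalid-sample runs inside a first-pass
#' fixation), signal loss (a long invalid run covering a configurable
#' fraction of the trial), skips (AOI never fixated), regressions (a
#' second-pass revisit after the following item), accidental entries (a
#' brief out-of-order fixation at list onset) and misarticulations
#' (accuracy flags in the voice annotations).  At most one eye artifact is
#' injected per item, so injected classes are disjoint by construction.
#'
#' @param aois The AOI rows of one list (subset of an `evs_stimuli` frame).
#' @param config An [sim_config()] object.
#' @param subject_id,trial_id Identifiers stored with the outputs.
#' @param subject_effect Additive subject intercept (ms) on offset EVS.
#' @param item_effects Named vector of additive item intercepts (ms).
#' @return A list of class `evs_trial` with elements `track` (data frame
#'   `time_ms`, `x_deg`, `y_deg`, `valid`), `voice` (`item_id`,
#'   `onset_ms`, `accurate`), `truth` (per-item ground truth incl.
#'   artifact labels), and the identifiers.
#' @examples
#' cfg <- sim_config(seed = 2, blink_rate = 0, skip_rate = 0,
#'                   regression_rate = 0, misarticulation_rate = 0,
#'                   accidental_entry_rate = 0, signal_loss_rate = 0)
#' stim <- build_stimulus_lists(cfg)
#' set.seed(2)
#' tr <- simulate_trial(stim[stim$list_id == "L01", ], cfg)
#' head(tr$truth)
#' @export
simulate_trial <- function(aois, config, subject_id = "S01",
                           trial_id = NULL, subject_effect = 0,
                           item_effects = NULL) {
  stopifnot(nrow(aois) > 0)
  if (length(unique(aois$list_id)) != 1L) {
    stop("simulate_trial expects the AOIs of exactly one list")
  }
  if (is.null(trial_id)) trial_id <- aois$list_id[1]
  geom <- config$geometry
  if (geom$min_spacing <= 0) {
    stop("AOI spacing incompatible with saccade model: min_spacing must be > 0")
  }
  dt <- config$dt_ms
  a <- aois[order(aois$slot), , drop = FALSE]
  n_items <- nrow(a)
  ctr <- aoi_centers(a)

  # per-item timing draws (random intercepts shift offset EVS additively)
  shifts <- rep(subject_effect, n_items)
  if (!is.null(item_effects)) {
    ie <- item_effects[a$item_id]
    ie[is.na(ie)] <- 0
    shifts <- shifts + ie
  }
  if (length(unique(shifts)) == 1L) {   # lists are condition-homogeneous
    timing <- simulate_item_timing(a$familiarity[1], a$length_class[1],
                                   config, n = n_items, shift = shifts[1])
  } else {
    timing <- do.call(rbind, lapply(seq_len(n_items), function(i) {
      simulate_item_timing(a$familiarity[i], a$length_class[i],
                           config, n = 1, shift = shifts[i])
    }))
  }

  # disjoint per-item eye-artifact assignment (priority: skip > regression
  # > blink), plus independent voice-side misarticulation kept disjoint
  # from eye artifacts so that ground-truth bookkeeping is exact
  rates <- config$rates
  skip <- stats::runif(n_items) < rates$skip
  regression <- stats::runif(n_items) < rates$regression
  blink <- stats::runif(n_items) < rates$blink
  misart <- stats::runif(n_items) < rates$misarticulation
  regression[n_items] <- FALSE            # only non-final items regress
  regression[skip] <- FALSE
  blink[skip | regression] <- FALSE
  misart[skip | regression | blink] <- FALSE
  accidental_item <- NA_integer_
  if (n_items >= 2 && stats::runif(1) < rates$accidental_entry) {
    cand <- setdiff(which(!skip & !regression & !blink & !misart), 1L)
    if (length(cand)) {
      accidental_item <- if (length(cand) == 1L) cand else
        cand[sample.int(length(cand), 1L)]
    }
  }
  signal_loss <- stats::runif(1) < rates$signal_loss

  # itinerary of attended positions: (aoi index or NA, duration in samples)
  start_pos <- c(a$x0[1] - geom$min_spacing - geom$aoi_width / 2,
                 (a$y0[1] + a$y1[1]) / 2)
  end_pos <- c(mean(range(c(a$x0, a$x1))), max(a$y1) + 5)
  itin_item <- integer(0); itin_n <- integer(0)
  push <- function(item, n_samp) {
    itin_item <<- c(itin_item, item)
    itin_n <<- c(itin_n, as.integer(n_samp))
  }
  push(NA_integer_, max(2L, round(config$start_fixation_ms / dt)))
  if (!is.na(accidental_item)) {
    push(-accidental_item, max(2L, round(config$accidental_fixation_ms / dt)))
  }
  n_regress <- max(2L, round(config$regression_fixation_ms / dt))
  n_gaze <- pmax(2L, as.integer(round(timing$gaze_ms / dt)))
  fixated <- which(!skip)
  # a regression on item r revisits r right after the first pass of the
  # next fixated item; without such an anchor the revisit would merge with
  # r's own first pass, so the label is dropped
  next_fixated <- function(r) {
    f <- fixated[fixated > r]
    if (length(f)) f[1] else NA_integer_
  }
  for (r in which(regression)) {
    if (is.na(next_fixated(r))) regression[r] <- FALSE
  }
  for (i in fixated) {
    push(i, n_gaze[i])
    for (r in which(regression)) {
      if (identical(next_fixated(r), i)) {
        push(-(n_items + r), n_regress)   # encoded second-pass visit
      }
    }
  }
  push(NA_integer_, max(2L, round(config$end_fixation_ms / dt)))

  # realize samples
  pos_of <- function(code) {
    if (is.na(code)) return(NULL)
    idx <- if (code > 0) code else (if (-code > n_items) -code - n_items else -code)
    c(ctr$x[idx], ctr$y[idx])
  }
  xs <- list(); cur <- start_pos
  seg_item <- integer(0)   # itinerary index per segment, NA for saccades
  seg_len <- integer(0)
  add_seg <- function(m, it) {
    seg_len <<- c(seg_len, nrow(m))
    seg_item <<- c(seg_item, it)
    xs[[length(xs) + 1L]] <<- m
  }
  for (k in seq_along(itin_item)) {
    target <- if (is.na(itin_item[k])) (if (k == 1L) start_pos else end_pos)
              else pos_of(itin_item[k])
    sac <- saccade_samples(cur, target, config)
    if (nrow(sac)) add_seg(sac, NA_integer_)
    nf <- itin_n[k]
    fx <- cbind(rep(target[1], nf), rep(target[2], nf))
    if (config$fixation_jitter_sd > 0) {
      fx <- fx + matrix(stats::rnorm(2 * nf, 0, config$fixation_jitter_sd),
                        ncol = 2)
    }
    add_seg(fx, k)
    cur <- target
  }
  pos <- do.call(rbind, xs)
  n_total <- nrow(pos)
  valid <- rep(TRUE, n_total)
  seg_start <- cumsum(c(0L, seg_len[-length(seg_len)]))  # 0-based

  # first-pass sample ranges per item (itinerary codes > 0)
  entry_idx <- rep(NA_integer_, n_items)
  exit_idx <- rep(NA_integer_, n_items)
  for (k in seq_along(itin_item)) {
    code <- itin_item[k]
    if (!is.na(code) && code > 0) {
      seg <- which(seg_item == k)
      entry_idx[code] <- seg_start[seg] + 1L
      exit_idx[code] <- seg_start[seg] + seg_len[seg]
    }
  }

  # blink injection inside first-pass fixations
  margin <- as.integer(ceiling(config$min_gaze_ms / dt)) + 5L
  n_blink <- as.integer(round(config$blink_ms / dt))
  for (i in which(blink)) {
    run <- exit_idx[i] - entry_idx[i] + 1L
    nb <- min(n_blink, run - 2L * margin)
    if (nb < 1L) { blink[i] <- FALSE; next }
    off <- margin + floor(stats::runif(1) * (run - nb - 2L * margin + 1))
    b0 <- entry_idx[i] + as.integer(off)
    valid[b0:(b0 + nb - 1L)] <- FALSE
  }
  if (signal_loss) {
    nl <- max(1L, as.integer(round(config$signal_loss_fraction * n_total)))
    s0 <- 1L + floor(stats::runif(1) * (n_total - nl + 1))
    valid[s0:(s0 + nl - 1L)] <- FALSE
  }
  pos[!valid, ] <- 0

  time_ms <- (seq_len(n_total) - 1L) * dt
  track <- data.frame(time_ms = time_ms, x_deg = pos[, 1], y_deg = pos[, 2],
                      valid = as.integer(valid))

  # ground truth + voice annotations (realized, sample-grid times)
  entry_ms <- (entry_idx - 1L) * dt
  gaze_real <- (exit_idx - entry_idx + 1L) * dt
  onset_ms <- entry_ms + gaze_real + timing$offset_evs_ms +
    config$voice_sync_offset_ms
  # skipped items are still named: anchor on the time the eyes pass by
  for (i in which(skip)) {
    later <- entry_ms[!is.na(entry_ms) &
                        seq_len(n_items) > i]
    anchor <- if (length(later)) min(later) else max(time_ms)
    cond <- lookup_condition(config, a$familiarity[i], a$length_class[i])
    onset_ms[i] <- anchor + cond$pt_mean + config$voice_sync_offset_ms
  }
  second_pass <- regression
  if (!is.na(accidental_item)) second_pass[accidental_item] <- TRUE
  truth <- data.frame(
    subject_id = subject_id, trial_id = trial_id, list_id = a$list_id,
    item_id = a$item_id, slot = a$slot, is_filler = a$is_filler,
    familiarity = a$familiarity, length_class = a$length_class,
    first_entry_ms = entry_ms, gaze_ms = gaze_real,
    voice_onset_ms = onset_ms,
    onset_evs_ms = onset_ms - entry_ms,
    offset_evs_ms = onset_ms - entry_ms - gaze_real,
    skip = skip, blink = blink, second_pass = second_pass,
    accidental_entry = seq_len(n_items) == ifelse(is.na(accidental_item), 0L,
                                                  accidental_item),
    misarticulated = misart,
    contaminated = signal_loss,
    stringsAsFactors = FALSE
  )
  voice <- data.frame(item_id = a$item_id, onset_ms = onset_ms,
                      accurate = !misart, stringsAsFactors = FALSE)
  structure(list(track = track, voice = voice, truth = truth,
                 subject_id = subject_id, trial_id = trial_id,
                 list_id = a$list_id[1]),
            class = "evs_trial")
}

#' Simulate a full multi-subject experiment
#'
#' Draws subject and item random intercepts from the configured variance
#' components, then simulates every subject reading every list.
#'
#' @param config An [sim_config()] object; `config$seed` (if non-`NULL`)
#'   seeds the generator so identical configurations give identical output.
#' @param stimuli Stimulus lists; built from `config` when `NULL`.
#' @param n_subjects Overrides `config$n_subjects` when given.
#' @param lists Optional character vector of list ids to simulate.
#' @return Object of class `evs_experiment`: list with `trials` (list of
#'   [simulate_trial()] results), `stimuli`, `config`, `subject_effects`,
#'   `item_effects`.
#' @export
simulate_experiment <- function(config, stimuli = NULL, n_subjects = NULL,
                                lists = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(stimuli)) stimuli <- build_stimulus_lists(config)
  if (is.null(n_subjects)) n_subjects <- config$n_subjects
  list_ids <- unique(stimuli$list_id)
  if (!is.null(lists)) list_ids <- intersect(list_ids, lists)
  subject_ids <- sprintf("S%02d", seq_len(n_subjects))
  subject_effects <- stats::setNames(
    stats::rnorm(n_subjects, 0, sqrt(config$subject_var)), subject_ids)
  items <- unique(stimuli$item_id)
  item_effects <- stats::setNames(
    stats::rnorm(length(items), 0, sqrt(config$item_var)), items)
  trials <- list()
  for (s in subject_ids) {
    for (l in list_ids) {
      trials[[paste(s, l, sep = "_")]] <- simulate_trial(
        stimuli[stimuli$list_id == l, , drop = FALSE], config,
        subject_id = s, trial_id = l,
        subject_effect = subject_effects[[s]], item_effects = item_effects)
    }
  }
  structure(list(trials = trials, stimuli = stimuli, config = config,
                 subject_effects = subject_effects,
                 item_effects = item_effects),
            class = "evs_experiment")
}

#' Simulate many independent trials of a single condition
#'
#' Convenience generator for condition-recovery analyses: one list layout
#' of the requested familiarity x length cell is reused across as many
#' independent trials (one synthetic subject each) as needed to reach
#' `n_items` experimental items.
#'
#' @inheritParams simulate_item_timing
#' @param n_items Minimum number of experimental (non-filler) items.
#' @return An `evs_experiment` object.
#' @export
simulate_condition_stream <- function(familiarity, length_class, config,
                                      n_items = 1000) {
  if (!is.null(config$seed)) set.seed(config$seed)
  grid <- config$grid
  rows <- if (length_class == "long") grid$rows_long else grid$rows_short
  cols <- if (length_class == "long") grid$cols_long else grid$cols_short
  aois <- aoi_grid(rows, cols, config$geometry)
  aois$list_id <- "L01"
  aois$familiarity <- familiarity
  aois$length_class <- length_class
  aois$regularity <- "regular"
  aois$is_filler <- aois$col == 1L | aois$slot == rows * cols
  aois$item_id <- sprintf("it_%02d", aois$slot)
  capacity <- sum(!aois$is_filler)
  n_trials <- ceiling(n_items / capacity)
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    sid <- sprintf("S%04d", k)
    trials[[k]] <- simulate_trial(aois, config, subject_id = sid,
                                  trial_id = "L01")
  }
  names(trials) <- sprintf("S%04d_L01", seq_len(n_trials))
  structure(list(trials = trials,
                 stimuli = structure(aois, class = c("evs_stimuli",
                                                     "data.frame")),
                 config = config,
                 subject_effects = NULL, item_effects = NULL),
            class = "evs_experiment")
}

## ---------------------------------------------------------------------------
## Model-level simulators
## ---------------------------------------------------------------------------

#' Simulate a balanced crossed random-intercepts dataset
#'
#' Generates item x subject offset-EVS responses from the Gaussian crossed
#' random-intercepts model: response = fixed-effect cell value + subject
#' intercept + item intercept + residual.  Fixed effects use treatment
#' coding with HF and long as reference levels; `coding = "main"` uses
#' only the main-effect coefficients, `coding = "full"` adds the
#' familiarity x length interaction terms.  Default coefficients and
#' variance components are the reported offset-EVS model estimates, with
#' the unprinted intercept set to the HF-long condition mean (191.4 ms).
#'
#' @param betas Named coefficients (ms): `intercept`, `LF`, `PW`, `short`,
#'   and for `coding = "full"` also `LF_short`, `PW_short`.
#' @param coding `"main"` or `"full"`.
#' @param variances Named variances (ms^2): `item`, `subject`, `residual`.
#' @param n_subjects,n_items_per_cell Balanced design size (6 conditions).
#' @param seed Optional seed.
#' @return Data frame with `subject_id`, `item_id`, `familiarity`,
#'   `length_class` (factors with HF/long reference levels) and `response`.
#' @examples
#' d <- simulate_lmm_dataset(n_subjects = 4, n_items_per_cell = 2, seed = 1)
#' head(d)
#' @export
simulate_lmm_dataset <- function(betas = c(intercept = 191.4, LF = -80.77,
                                           PW = -202.20, short = 134.80,
                                           LF_short = 66.00,
                                           PW_short = 130.53),
                                 coding = c("main", "full"),
                                 variances = c(item = 8323, subject = 6093,
                                               residual = 16684),
                                 n_subjects = 36, n_items_per_cell = 40,
                                 seed = NULL) {
  coding <- match.arg(coding)
  if (any(variances < 0)) stop("variances must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  fam_levels <- c("HF", "LF", "PW")
  len_levels <- c("long", "short")
  cells <- expand.grid(familiarity = fam_levels, length_class = len_levels,
                       stringsAsFactors = FALSE)
  cell_mean <- function(fam, len) {
    m <- betas[["intercept"]]
    if (fam == "LF") m <- m + betas[["LF"]]
    if (fam == "PW") m <- m + betas[["PW"]]
    if (len == "short") {
      m <- m + betas[["short"]]
      if (coding == "full") {
        if (fam == "LF") m <- m + betas[["LF_short"]]
        if (fam == "PW") m <- m + betas[["PW_short"]]
      }
    }
    m
  }
  items <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
    data.frame(
      item_id = sprintf("%s_%s_%03d", cells$familiarity[ci],
                        cells$length_class[ci], seq_len(n_items_per_cell)),
      familiarity = cells$familiarity[ci],
      length_class = cells$length_class[ci],
      mu = cell_mean(cells$familiarity[ci], cells$length_class[ci]),
      stringsAsFactors = FALSE)
  }))
  subject_ids <- sprintf("S%02d", seq_len(n_subjects))
  b_subj <- stats::setNames(
    stats::rnorm(n_subjects, 0, sqrt(variances[["subject"]])), subject_ids)
  b_item <- stats::setNames(
    stats::rnorm(nrow(items), 0, sqrt(variances[["item"]])), items$item_id)
  d <- merge(data.frame(subject_id = subject_ids, stringsAsFactors = FALSE),
             items, by = NULL)
  d$response <- d$mu + b_subj[d$subject_id] + b_item[d$item_id] +
    stats::rnorm(nrow(d), 0, sqrt(variances[["residual"]]))
  d$mu <- NULL
  d$familiarity <- factor(d$familiarity, levels = fam_levels)
  d$length_class <- factor(d$length_class, levels = len_levels)
  d[order(d$subject_id, d$item_id), ]
}

#' Simulate per-subject reading-velocity scores
#'
#' Velocity (items named in a fixed-time concurrent naming test) is a
#' linear function of the subject's mean offset EVS plus Gaussian noise,
#' capped at the test's item count.
#'
#' @param subject_summaries Data frame with one row per subject and the
#'   predictor column named by `predictor`.
#' @param slope,intercept,noise_sd Linear-model parameters.
#' @param max_score Cap on the score (default 75, the test item count).
#' @param predictor Name of the predictor column.
#' @return `subject_summaries` with a `velocity` column appended.
#' @export
simulate_reading_velocity <- function(subject_summaries, slope = 0.05,
                                      intercept = 30, noise_sd = 5,
                                      max_score = 75,
                                      predictor = "mean_offset_evs") {
  stopifnot(is.data.frame(subject_summaries),
            predictor %in% names(subject_summaries))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  x <- subject_summaries[[predictor]]
  v <- intercept + slope * x + stats::rnorm(length(x), 0, noise_sd)
  subject_summaries$velocity <- pmin(v, max_score)
  subject_summaries
}
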