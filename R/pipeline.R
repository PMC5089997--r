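#' Default analysis parameters
#'
#' Thresholds of the analysis chain: the I-VT velocity threshold (30
#' deg/s), minimum fixation duration (50 ms), blink/lost boundary
#' (500 ms), velocity smoothing window (5 samples), the strict 25%
#' signal-loss and 25% contaminated-trial exclusion fractions, the
#' per-condition outlier z cutoff (3 SD), the articulatory-programming
#' reference (150 ms) and the accidental-entry window (1000 ms).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of parameters.
#' @export
analysis_params <- function(...) {
  p <- list(velocity_threshold = 30, min_fixation_ms = 50,
            blink_max_ms = 500, velocity_window = 5,
            trial_threshold = 0.25, subject_threshold = 0.25,
            z_threshold = 3, motor_reference_ms = 150,
            accidental_window_ms = 1000)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown analysis parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

#' Analyze one trial: events, visits, flags, measures
#'
#' Runs event detection, AOI visit assignment, first-pass extraction,
#' artifact flagging and EVS computation for a single trial.
#'
#' @param trial An `evs_trial` object (or a list with `track`, `voice`,
#'   `subject_id`, `trial_id`, `list_id`).
#' @param aois AOI rows of the presented list.
#' @param params [analysis_params()] list.
#' @return List with `events`, `visits`, `flags`, `measures`.
#' @export
analyze_trial <- function(trial, aois, params = analysis_params()) {
  events <- detect_events(trial$track,
                          velocity_threshold = params$velocity_threshold,
                          min_fixation_ms = params$min_fixation_ms,
                          blink_max_ms = params$blink_max_ms,
                          velocity_window = params$velocity_window,
                          trial_id = trial$trial_id)
  visits <- assign_visits(events, aois)
  fp <- first_pass_gaze(visits, items = aois$item_id)
  flags <- flag_item_artifacts(visits, aois, trial$voice, events,
                               accidental_window_ms = params$accidental_window_ms)
  measures <- compute_measures(flags, fp, trial$voice,
                               subject_id = trial$subject_id,
                               list_id = trial$list_id)
  list(events = events, visits = visits, flags = flags, measures = measures)
}

#' Analyze a set of simulated or imported trials end to end
#'
#' Applies [analyze_trial()] to every trial, assembles the item x subject
#' measures table, computes contamination flags, runs the exclusion
#' cascade and summarizes conditions.
#'
#' @param experiment An `evs_experiment` (or list with `trials` and
#'   `stimuli`).
#' @param params [analysis_params()] list.
#' @return List of class `evs_analysis`: `measures` (screened, with
#'   exclusion columns), `report` (`evs_exclusion_report`),
#'   `contamination`, `condition_summary`, `events`, `visits`.
#' @export
analyze_experiment <- function(experiment, params = analysis_params()) {
  stim <- experiment$stimuli
  res <- lapply(experiment$trials, function(tr) {
    aois <- stim[stim$list_id == tr$list_id, , drop = FALSE]
    analyze_trial(tr, aois, params)
  })
  measures <- do.call(rbind, lapply(res, `[[`, "measures"))
  events <- do.call(rbind, lapply(seq_along(res), function(i) {
    ev <- res[[i]]$events
    ev$subject_id <- experiment$trials[[i]]$subject_id
    ev
  }))
  visits <- do.call(rbind, lapply(seq_along(res), function(i) {
    vs <- res[[i]]$visits
    if (nrow(vs)) {
      vs$subject_id <- experiment$trials[[i]]$subject_id
      vs$trial_id <- experiment$trials[[i]]$trial_id
    }
    vs
  }))
  rownames(measures) <- NULL
  contamination <- flag_contamination(contamination_stats(experiment$trials),
                                      trial_threshold = params$trial_threshold,
                                      subject_threshold = params$subject_threshold)
  screened <- apply_cascade(measures, contamination,
                            z_threshold = params$z_threshold)
  summary_tab <- if (screened$report$retained_offset_n == 0) NULL else
    summarize_conditions(screened$measures,
                         motor_reference_ms = params$motor_reference_ms)
  structure(list(measures = screened$measures, report = screened$report,
                 contamination = contamination,
                 condition_summary = summary_tab,
                 events = events, visits = visits, params = params),
            class = "evs_analysis")
}

#' Per-subject EVS summaries over retained records
#'
#' @param measures Screened measures (with `retained_offset` /
#'   `retained_gtpt` columns).
#' @return Data frame `subject_id`, `n`, `mean_offset_evs`, `mean_gt_pt`.
#' @export
subject_summaries <- function(measures) {
  ids <- sort(unique(measures$subject_id))
  rows <- lapply(ids, function(s) {
    off <- measures$offset_evs_ms[measures$subject_id == s &
                                    measures$retained_offset]
    gtp <- measures$gt_pt[measures$subject_id == s & measures$retained_gtpt]
    data.frame(subject_id = s, n = length(off),
               mean_offset_evs = if (length(off)) mean(off) else NA_real_,
               mean_gt_pt = if (length(gtp)) mean(gtp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the complete simulate-and-analyze pipeline
#'
#' Simulates an experiment from `config`, writes all raw interchange
#' files (gaze TSV per trial, voice CSV per trial, AOI CSV, ground-truth
#' CSV), re-reads them, runs the full analysis (events, visits, measures,
#' exclusion cascade, condition summary), fits the offset-EVS and GT/PT
#' mixed-model ladders when the design is large enough, regresses
#' simulated reading-velocity scores on the subject summaries, and writes
#' every artifact to `out_dir`.  Identical `config` (including seed)
#' yields byte-identical outputs.
#'
#' @param config [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param params [analysis_params()] list.
#' @param n_subjects,lists Optional design subsets passed to
#'   [simulate_experiment()].
#' @param velocity List of reading-velocity generator parameters
#'   (`slope`, `intercept`, `noise_sd`, `max_score`).
#' @param write_raw Write per-trial raw gaze/voice files and read them
#'   back (default TRUE; set FALSE to analyze in memory).
#' @param fit_models Fit the LMM ladders (needs >= 2 subjects and items).
#' @param verbose Emit progress messages.
#' @return List of class `evs_pipeline`: the `analysis`, `lmm` fits,
#'   `velocity_fit`, `subject_summaries`, `out_dir` and `config`.
#' @export
run_pipeline <- function(config, out_dir, params = analysis_params(),
                         n_subjects = NULL, lists = NULL,
                         velocity = list(slope = 0.05, intercept = 30,
                                         noise_sd = 5, max_score = 75),
                         write_raw = TRUE, fit_models = TRUE,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exp <- simulate_experiment(config, n_subjects = n_subjects, lists = lists)
  say("simulated %d trials", length(exp$trials))
  if (write_raw) {
    raw_dir <- file.path(out_dir, "raw")
    dir.create(raw_dir, showWarnings = FALSE)
    write_aoi_csv(exp$stimuli, file.path(raw_dir, "aoi.csv"))
    truth <- do.call(rbind, lapply(exp$trials, `[[`, "truth"))
    rownames(truth) <- NULL
    write_table_csv(truth, file.path(raw_dir, "ground_truth.csv"))
    for (nm in names(exp$trials)) {
      tr <- exp$trials[[nm]]
      write_gaze_tsv(tr$track, file.path(raw_dir, paste0("gaze_", nm, ".tsv")))
      write_voice_csv(tr$voice, file.path(raw_dir, paste0("voice_", nm, ".csv")))
    }
    stim <- read_aoi_csv(file.path(raw_dir, "aoi.csv"))
    trials <- lapply(names(exp$trials), function(nm) {
      tr <- exp$trials[[nm]]
      structure(list(
        track = read_gaze_tsv(file.path(raw_dir, paste0("gaze_", nm, ".tsv"))),
        voice = read_voice_csv(file.path(raw_dir, paste0("voice_", nm, ".csv"))),
        truth = tr$truth, subject_id = tr$subject_id,
        trial_id = tr$trial_id, list_id = tr$list_id), class = "evs_trial")
    })
    names(trials) <- names(exp$trials)
    exp_in <- structure(list(trials = trials, stimuli = stim,
                             config = config), class = "evs_experiment")
  } else {
    exp_in <- exp
  }
  analysis <- analyze_experiment(exp_in, params)
  say("retained %d / %d records (offset EVS)",
      analysis$report$retained_offset_n, analysis$report$input_n)
  write_table_csv(analysis$events, file.path(out_dir, "events.csv"))
  write_table_csv(analysis$visits, file.path(out_dir, "visits.csv"))
  write_table_csv(analysis$measures, file.path(out_dir, "measures.csv"))
  if (!is.null(analysis$condition_summary)) {
    write_table_csv(analysis$condition_summary,
                    file.path(out_dir, "condition_summary.csv"))
  }
  write_exclusion_report(analysis$report, file.path(out_dir, "exclusions.json"))

  lmm <- NULL
  meas <- analysis$measures
  if (fit_models && length(unique(meas$subject_id)) >= 2 &&
      length(unique(meas$item_id)) >= 2) {
    d_off <- meas[meas$retained_offset, , drop = FALSE]
    d_off$familiarity <- factor(d_off$familiarity, c("HF", "LF", "PW"))
    d_off$length_class <- factor(d_off$length_class, c("long", "short"))
    lmm <- list(offset = evs_lrt_ladder(d_off, "offset_evs_ms"))
    d_gtp <- meas[meas$retained_gtpt, , drop = FALSE]
    d_gtp$familiarity <- factor(d_gtp$familiarity, c("HF", "LF", "PW"))
    d_gtp$length_class <- factor(d_gtp$length_class, c("long", "short"))
    lmm$gtpt <- evs_lrt_ladder(d_gtp, "gt_pt")
    for (resp in c("offset", "gtpt")) {
      fits <- lmm[[resp]]$fits
      tab <- rbind(
        cbind(model = "additive", fits$additive$fixed),
        cbind(model = "interaction", fits$interaction$fixed))
      tab$significant <- abs(tab$t) > 2
      write_table_csv(tab, file.path(out_dir, paste0("lmm_", resp, ".csv")))
      write_table_csv(lmm[[resp]]$tests,
                      file.path(out_dir, paste0("lrt_", resp, ".csv")))
    }
    say("fitted LMM ladders")
  }

  subj <- subject_summaries(meas)
  subj <- subj[!is.na(subj$mean_offset_evs), , drop = FALSE]
  vel_fit <- NULL
  if (nrow(subj) >= 3 && stats::sd(subj$mean_offset_evs) > 0) {
    subj <- simulate_reading_velocity(subj, slope = velocity$slope,
                                      intercept = velocity$intercept,
                                      noise_sd = velocity$noise_sd,
                                      max_score = velocity$max_score)
    vel_fit <- velocity_regression(subj)
    write_table_csv(subj, file.path(out_dir, "subject_summaries.csv"))
  }
  out <- structure(list(analysis = analysis, lmm = lmm,
                        velocity_fit = vel_fit, subject_summaries = subj,
                        out_dir = out_dir, config = config),
                   class = "evs_pipeline")
  writeLines(render_report(out_dir), file.path(out_dir, "report.txt"))
  out
}

render_report <- function(out_dir) {
  need <- c("exclusions.json", "measures.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing)) {
    stop("missing pipeline artifact(s) in ", out_dir, ": ",
         paste(missing, collapse = ", "))
  }
  excl <- jsonlite::read_json(file.path(out_dir, "exclusions.json"),
                              simplifyVector = TRUE)
  lines <- c("Eye-voice span pipeline report",
             strrep("=", 34), "")
  lines <- c(lines, "Exclusion accounting:",
             sprintf("  input records: %d", excl$input_n))
  for (r in names(excl$counts)) {
    lines <- c(lines, sprintf("  %-20s %d", r, excl$counts[[r]]))
  }
  lines <- c(lines,
             sprintf("  %-20s %d", "outlier_offset_evs", excl$outlier_offset_n),
             sprintf("  %-20s %d", "outlier_gt_pt", excl$outlier_gtpt_n),
             sprintf("  retained: offset EVS %d, GT/PT %d",
                     excl$retained_offset_n, excl$retained_gtpt_n),
             sprintf("  check: %d (input) = %d (retained) + %d (excluded)",
                     excl$input_n, excl$retained_offset_n,
                     sum(unlist(excl$counts)) + excl$outlier_offset_n), "")
  if (excl$retained_offset_n == 0) {
    lines <- c(lines, "*** no retained records ***", "")
    return(lines)
  }
  cs <- read_table_csv(file.path(out_dir, "condition_summary.csv"))
  lines <- c(lines, "Condition summary (offset EVS ms, GT/PT):")
  for (i in seq_len(nrow(cs))) {
    tag <- if (cs$mean_offset_evs[i] < 0) " [voice-eye span]"
           else if (cs$exceeds_motor_reference[i]) " [> motor reference]"
           else ""
    lines <- c(lines, sprintf(
      "  %-3s %-6s offset %8.1f (%.1f)  GT/PT %5.2f (%.2f)  crossing p%d%s",
      cs$familiarity[i], cs$length_class[i], cs$mean_offset_evs[i],
      cs$sd_offset_evs[i], cs$mean_gt_pt[i], cs$sd_gt_pt[i],
      cs$crossing_percentile_gtpt[i], tag))
  }
  for (resp in c("offset", "gtpt")) {
    fl <- file.path(out_dir, paste0("lmm_", resp, ".csv"))
    if (file.exists(fl)) {
      tab <- read_table_csv(fl)
      lines <- c(lines, "", sprintf("Fixed effects (%s):", resp))
      for (i in seq_len(nrow(tab))) {
        lines <- c(lines, sprintf("  %-11s %-28s %9.3f (SE %.3f) t %6.2f%s",
                                  tab$model[i], tab$term[i], tab$estimate[i],
                                  tab$se[i], tab$t[i],
                                  if (tab$significant[i]) " *" else ""))
      }
      lt <- read_table_csv(file.path(out_dir, paste0("lrt_", resp, ".csv")))
      for (i in seq_len(nrow(lt))) {
        lines <- c(lines, sprintf("  LRT %-12s chi2(%d) = %.2f, p = %.4g",
                                  lt$effect[i], lt$df[i], lt$chi2[i], lt$p[i]))
      }
    }
  }
  lines
}

#' Render a human-readable report from pipeline artifacts
#'
#' Reads the artifact files previously written by [run_pipeline()] and
#' renders the condition summary, mixed-model tables and exclusion
#' accounting as text, flagging conditions with a negative mean offset
#' EVS (voice-eye span) and conditions whose mean exceeds the
#' articulatory-programming reference.
#'
#' @param out_dir Directory holding the pipeline artifacts.
#' @param path Optional file to write the report to (defaults to
#'   `report.txt` inside `out_dir`).
#' @return The report lines, invisibly; also prints them.
#' @export
make_report <- function(out_dir, path = file.path(out_dir, "report.txt")) {
  lines <- render_report(out_dir)
  writeLines(lines, path)
  cat(lines, sep = "\n")
  invisible(lines)
}
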