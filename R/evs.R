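#' Item-level eye-voice span measures
#'
#' Joins first-pass eye measures, artifact flags and voice onsets into one
#' record per (subject, item) and computes the span algebra:
#' onset EVS = voice onset - first entry (the item's processing time PT),
#' offset EVS = onset EVS - first-pass gaze time, and
#' GT/PT = first-pass gaze time / onset EVS (defined for onset EVS > 0).
#' Positive offset EVS (equivalently GT/PT < 1) is eye-voice span — the
#' eyes have moved on before naming begins; negative offset EVS (GT/PT >
#' 1) is voice-eye span; zero is the boundary.  Records whose voice onset
#' precedes first entry get onset EVS <= 0 and are kept but flagged
#' `invalid_onset` for downstream exclusion.
#'
#' Only non-filler items are reported.
#'
#' @param item_flags Output of [flag_item_artifacts()] for one trial.
#' @param first_pass Output of [first_pass_gaze()] for the same trial.
#' @param voice Voice annotations (`item_id`, `onset_ms`, `accurate`).
#' @param subject_id,list_id Identifiers copied into the output.
#' @return Data frame of `ItemMeasure` records: identifiers, condition,
#'   `first_entry_ms`, `first_pass_gaze_ms`, `voice_onset_ms`,
#'   `onset_evs_ms`, `offset_evs_ms`, `gt_pt`, `span_class`
#'   (`"eye_voice"`, `"voice_eye"` or `"boundary"`), `invalid_onset` and
#'   the artifact flags.
#' @export
compute_measures <- function(item_flags, first_pass, voice,
                             subject_id = "S01", list_id = "L01") {
  m <- item_flags[!item_flags$is_filler, , drop = FALSE]
  fp <- first_pass[match(m$item_id, first_pass$item_id), , drop = FALSE]
  vo <- voice[match(m$item_id, voice$item_id), , drop = FALSE]
  out <- data.frame(
    subject_id = subject_id, list_id = list_id, item_id = m$item_id,
    familiarity = m$familiarity, length_class = m$length_class,
    first_entry_ms = fp$first_entry_ms,
    first_pass_gaze_ms = fp$first_pass_gaze_ms,
    voice_onset_ms = vo$onset_ms,
    stringsAsFactors = FALSE)
  out$onset_evs_ms <- out$voice_onset_ms - out$first_entry_ms
  out$offset_evs_ms <- out$onset_evs_ms - out$first_pass_gaze_ms
  out$gt_pt <- ifelse(!is.na(out$onset_evs_ms) & out$onset_evs_ms > 0,
                      out$first_pass_gaze_ms / out$onset_evs_ms, NA_real_)
  out$span_class <- ifelse(is.na(out$offset_evs_ms), NA_character_,
                           ifelse(out$offset_evs_ms > 0, "eye_voice",
                                  ifelse(out$offset_evs_ms < 0, "voice_eye",
                                         "boundary")))
  out$invalid_onset <- !is.na(out$onset_evs_ms) & out$onset_evs_ms <= 0
  for (fl in c("skip", "second_pass", "accidental_entry", "blink_overlap",
               "misarticulated")) {
    out[[fl]] <- m[[fl]]
  }
  out
}

#' Percentile at which a span measure crosses its boundary
#'
#' Scans the integer percentiles 1..100 and returns the smallest p whose
#' empirical p-th quantile (linear interpolation between order statistics)
#' lies past the boundary: below 0 for `direction = "offset"` (offset EVS
#' turning into voice-eye span) or above 1 for `direction = "gtpt"`
#' (GT/PT exceeding 1).  Returns 100 when no value crosses.
#'
#' @param values Numeric vector (NAs dropped); must be non-empty.
#' @param direction `"offset"` or `"gtpt"`.
#' @param quantile_type Passed to [stats::quantile()] (default 7, linear
#'   interpolation).
#' @return Integer percentile in 1..100.
#' @examples
#' crossing_percentile(c(5, 10, 20), "offset")       # 100: never negative
#' crossing_percentile(c(-5, 1:96), "offset")        # small percentile
#' @export
crossing_percentile <- function(values, direction = c("offset", "gtpt"),
                                quantile_type = 7) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  if (!length(values)) stop("crossing_percentile: empty input")
  past <- if (direction == "offset") {
    function(q) q < 0
  } else {
    function(q) q > 1
  }
  qs <- stats::quantile(values, probs = (1:100) / 100, type = quantile_type,
                        names = FALSE)
  hit <- which(past(qs))
  if (length(hit)) hit[1L] else 100L
}

#' Condition-level summary of offset EVS and GT/PT
#'
#' Mean and SD of offset EVS and GT/PT per familiarity x length condition,
#' the crossing percentiles of both measures, the mean span class, and a
#' comparison of mean offset EVS against the articulatory (motor)
#' programming reference duration.  When the measures carry
#' `retained_offset` / `retained_gtpt` columns (added by [apply_cascade()])
#' each measure is summarized over its own retained records; otherwise all
#' non-missing records are used.
#'
#' @param measures Item-measure data frame.
#' @param motor_reference_ms Reference duration of the final articulatory
#'   programming stage (default 150 ms).
#' @return Data frame with one row per condition: `familiarity`,
#'   `length_class`, `n_offset`, `mean_offset_evs`, `sd_offset_evs`,
#'   `n_gtpt`, `mean_gt_pt`, `sd_gt_pt`, `crossing_percentile_offset`,
#'   `crossing_percentile_gtpt`, `span_class` (of the condition mean) and
#'   `exceeds_motor_reference`.
#' @export
summarize_conditions <- function(measures, motor_reference_ms = 150) {
  ro <- if ("retained_offset" %in% names(measures)) measures$retained_offset
        else !is.na(measures$offset_evs_ms)
  rg <- if ("retained_gtpt" %in% names(measures)) measures$retained_gtpt
        else !is.na(measures$gt_pt)
  cells <- unique(measures[, c("familiarity", "length_class")])
  cells <- cells[order(cells$familiarity, cells$length_class), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    sel <- measures$familiarity == cells$familiarity[ci] &
      measures$length_class == cells$length_class[ci]
    off <- measures$offset_evs_ms[sel & ro]
    gtp <- measures$gt_pt[sel & rg]
    if (length(off) < 2L) {
      stop("condition ", condition_key(cells$familiarity[ci],
                                       cells$length_class[ci]),
           " has fewer than 2 retained records")
    }
    m_off <- mean(off)
    data.frame(
      familiarity = cells$familiarity[ci],
      length_class = cells$length_class[ci],
      n_offset = length(off), mean_offset_evs = m_off,
      sd_offset_evs = stats::sd(off),
      n_gtpt = length(gtp),
      mean_gt_pt = if (length(gtp)) mean(gtp) else NA_real_,
      sd_gt_pt = if (length(gtp) > 1L) stats::sd(gtp) else NA_real_,
      crossing_percentile_offset = crossing_percentile(off, "offset"),
      crossing_percentile_gtpt = if (length(gtp))
        crossing_percentile(gtp, "gtpt") else NA_integer_,
      span_class = if (m_off > 0) "eye_voice"
                   else if (m_off < 0) "voice_eye" else "boundary",
      exceeds_motor_reference = m_off > motor_reference_ms,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "motor_reference_ms") <- motor_reference_ms
  out
}
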