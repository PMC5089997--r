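#' Z-score outlier flags within condition groups
#'
#' Flags values lying more than `z_threshold` group standard deviations
#' from their group mean.  Degenerate groups (SD 0) and missing values are
#' never flagged.  Group statistics can be frozen (passed in) so that
#' re-application to the filtered data is idempotent.
#'
#' @param values Numeric vector.
#' @param group Grouping vector (condition labels), same length.
#' @param z_threshold Cutoff in SD units (default 3).
#' @param stats_table Optional frozen statistics: data frame with columns
#'   `group`, `mean`, `sd` as returned in the `"stats"` attribute of a
#'   previous call.
#' @return Logical vector of outlier flags, with the group statistics used
#'   attached as attribute `"stats"`.
#' @export
outlier_filter <- function(values, group, z_threshold = 3,
                           stats_table = NULL) {
  stopifnot(length(values) == length(group))
  if (is.null(stats_table)) {
    gs <- split(values, group)
    stats_table <- data.frame(
      group = names(gs),
      mean = vapply(gs, function(v) mean(v, na.rm = TRUE), numeric(1)),
      sd = vapply(gs, function(v) stats::sd(v[!is.na(v)]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  idx <- match(as.character(group), stats_table$group)
  mu <- stats_table$mean[idx]
  sg <- stats_table$sd[idx]
  flags <- !is.na(values) & !is.na(sg) & sg > 0 &
    abs(values - mu) > z_threshold * sg
  attr(flags, "stats") <- stats_table
  flags
}

#' Apply the full exclusion cascade
#'
#' Removes item x subject records in a fixed order, attributing each
#' removal to exactly the first matching reason: excluded subject (too
#' many contaminated trials), contaminated trial (too much signal loss),
#' misarticulation, blink, skip, accidental entry, second-pass reading,
#' invalid onset (onset EVS <= 0), and finally per-measure statistical
#' outliers.  Outliers are flagged separately on offset EVS and on GT/PT
#' (per condition, z-score rule on the records surviving all earlier
#' stages), so the two measures can retain different record counts.
#'
#' @param measures Item-measure data frame from [compute_measures()]
#'   (rows from many trials bound together).
#' @param contamination Optional [flag_contamination()] result; trials are
#'   matched on `subject_id` + `list_id`.
#' @param z_threshold Outlier cutoff in group-SD units (default 3).
#' @param outlier_stats Optional list with elements `offset` and `gtpt`:
#'   frozen group statistics for [outlier_filter()] (for idempotent
#'   re-application).
#' @return List of class `evs_screen`: `measures` (input plus
#'   `exclusion_reason`, `retained_offset`, `retained_gtpt`) and `report`
#'   (an `evs_exclusion_report`: `input_n`, named reason `counts`,
#'   `retained_offset_n`, `retained_gtpt_n`, and the frozen
#'   `outlier_stats`).
#' @export
apply_cascade <- function(measures, contamination = NULL, z_threshold = 3,
                          outlier_stats = NULL) {
  n <- nrow(measures)
  reason <- rep(NA_character_, n)
  hit <- function(flag, label) {
    sel <- is.na(reason) & !is.na(flag) & flag
    reason[sel] <<- label
  }
  if (!is.null(contamination)) {
    bad_subj <- contamination$subjects$subject_id[contamination$subjects$excluded]
    hit(measures$subject_id %in% bad_subj, "excluded_subject")
    ct <- contamination$trials
    bad_trials <- paste(ct$subject_id, ct$trial_id)[ct$contaminated]
    hit(paste(measures$subject_id, measures$list_id) %in% bad_trials,
        "contaminated_trial")
  }
  hit(measures$misarticulated, "misarticulated")
  hit(measures$blink_overlap, "blink")
  hit(measures$skip, "skip")
  hit(measures$accidental_entry, "accidental_entry")
  hit(measures$second_pass, "second_pass")
  hit(measures$invalid_onset, "invalid_onset")
  clean <- is.na(reason)

  off_flags <- rep(FALSE, n)
  gtpt_flags <- rep(FALSE, n)
  grp <- condition_key(measures$familiarity, measures$length_class)
  o_fl <- outlier_filter(measures$offset_evs_ms[clean], grp[clean],
                         z_threshold, stats_table = outlier_stats$offset)
  off_flags[clean] <- o_fl
  off_stats <- attr(o_fl, "stats")
  g_fl <- outlier_filter(measures$gt_pt[clean], grp[clean], z_threshold,
                         stats_table = outlier_stats$gtpt)
  gtpt_flags[clean] <- g_fl
  gtpt_stats <- attr(g_fl, "stats")

  measures$exclusion_reason <- reason
  measures$retained_offset <- clean & !off_flags
  measures$retained_gtpt <- clean & !gtpt_flags & !is.na(measures$gt_pt)

  reasons <- c("excluded_subject", "contaminated_trial", "misarticulated",
               "blink", "skip", "accidental_entry", "second_pass",
               "invalid_onset")
  counts <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  report <- structure(list(
    input_n = n,
    counts = counts,
    outlier_offset_n = sum(clean & off_flags),
    outlier_gtpt_n = sum(clean & (gtpt_flags | is.na(measures$gt_pt))),
    retained_offset_n = sum(measures$retained_offset),
    retained_gtpt_n = sum(measures$retained_gtpt),
    outlier_stats = list(offset = off_stats, gtpt = gtpt_stats),
    z_threshold = z_threshold
  ), class = "evs_exclusion_report")
  structure(list(measures = measures, report = report),
            class = "evs_screen")
}

#' @export
print.evs_exclusion_report <- function(x, ...) {
  cat("Exclusion cascade report\n")
  cat(sprintf("  input records: %d\n", x$input_n))
  for (r in names(x$counts)) {
    cat(sprintf("  %-18s %d\n", r, x$counts[[r]]))
  }
  cat(sprintf("  outlier (offset EVS) %d -> retained %d\n",
              x$outlier_offset_n, x$retained_offset_n))
  cat(sprintf("  outlier/undefined (GT/PT) %d -> retained %d\n",
              x$outlier_gtpt_n, x$retained_gtpt_n))
  invisible(x)
}

#' Serialize an exclusion report to JSON
#'
#' @param report An `evs_exclusion_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  payload <- list(
    input_n = report$input_n,
    counts = as.list(report$counts),
    outlier_offset_n = report$outlier_offset_n,
    outlier_gtpt_n = report$outlier_gtpt_n,
    retained_offset_n = report$retained_offset_n,
    retained_gtpt_n = report$retained_gtpt_n,
    z_threshold = report$z_threshold)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
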