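#' Assign fixations to AOI visits
#'
#' Walks the ordered sequence of fixation events (discarded fixations and
#' all non-fixation events are ignored) and groups maximal runs of
#' consecutive fixations whose centroids fall inside the same AOI into
#' visits.  Any fixation landing outside the AOI — in another AOI or in no
#' AOI — ends the current visit; re-entering an AOI later opens a new
#' visit with an incremented pass index.  Membership is decided by the
#' fixation centroid.
#'
#' @param events Event data frame from [detect_events()].
#' @param aois AOI rows of the presented list (an `evs_stimuli` subset);
#'   rectangles must not overlap.
#' @return Data frame of visits: `item_id`, `pass`, `entry_ms`, `exit_ms`,
#'   `gaze_ms` (summed fixation durations), `n_fixations`.
#' @examples
#' cfg <- sim_config(seed = 3, blink_rate = 0, skip_rate = 0,
#'                   regression_rate = 0, misarticulation_rate = 0,
#'                   accidental_entry_rate = 0, signal_loss_rate = 0)
#' stim <- build_stimulus_lists(cfg)
#' set.seed(3)
#' tr <- simulate_trial(stim[stim$list_id == "L01", ], cfg)
#' ev <- detect_events(tr$track)
#' head(assign_visits(ev, stim[stim$list_id == "L01", ]))
#' @export
assign_visits <- function(events, aois) {
  check_aoi_overlap(aois)
  fx <- events[events$kind == "fixation", , drop = FALSE]
  if (nrow(fx) == 0L) {
    return(data.frame(item_id = character(), pass = integer(),
                      entry_ms = numeric(), exit_ms = numeric(),
                      gaze_ms = numeric(), n_fixations = integer(),
                      stringsAsFactors = FALSE))
  }
  lab <- rep(NA_character_, nrow(fx))
  for (k in seq_len(nrow(aois))) {
    inside <- fx$x >= aois$x0[k] & fx$x <= aois$x1[k] &
      fx$y >= aois$y0[k] & fx$y <= aois$y1[k]
    lab[inside] <- aois$item_id[k]
  }
  key <- ifelse(is.na(lab), "<none>", lab)
  runs <- run_bounds(key)
  runs <- runs[runs$value != "<none>", , drop = FALSE]
  if (nrow(runs) == 0L) {
    return(data.frame(item_id = character(), pass = integer(),
                      entry_ms = numeric(), exit_ms = numeric(),
                      gaze_ms = numeric(), n_fixations = integer(),
                      stringsAsFactors = FALSE))
  }
  visits <- data.frame(
    item_id = runs$value,
    entry_ms = fx$t_start_ms[runs$start],
    exit_ms = fx$t_end_ms[runs$end],
    gaze_ms = vapply(seq_len(nrow(runs)), function(i) {
      idx <- runs$start[i]:runs$end[i]
      sum(fx$t_end_ms[idx] - fx$t_start_ms[idx])
    }, numeric(1)),
    n_fixations = runs$end - runs$start + 1L,
    stringsAsFactors = FALSE)
  visits$pass <- stats::ave(seq_len(nrow(visits)), visits$item_id,
                            FUN = seq_along)
  visits[, c("item_id", "pass", "entry_ms", "exit_ms", "gaze_ms",
             "n_fixations")]
}

check_aoi_overlap <- function(aois) {
  n <- nrow(aois)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (aois$x0[i] < aois$x1[j] && aois$x0[j] < aois$x1[i] &&
          aois$y0[i] < aois$y1[j] && aois$y0[j] < aois$y1[i]) {
        stop("overlapping AOIs: ", aois$item_id[i], " and ", aois$item_id[j])
      }
    }
  }
  invisible(TRUE)
}

#' First-entry time and first-pass gaze time per item
#'
#' The first-pass gaze time of an item is the summed duration of the
#' fixations of its pass-1 visit (intra-visit saccade and blink time is
#' excluded); the first entry is the onset of the first fixation of that
#' visit.  Items without any visit are skipped items and get `NA`.
#'
#' @param visits Visit data frame from [assign_visits()].
#' @param items Character vector of item ids to report (defaults to the
#'   visited ones).
#' @return Data frame `item_id`, `first_entry_ms`, `first_pass_gaze_ms`.
#' @export
first_pass_gaze <- function(visits, items = NULL) {
  if (is.null(items)) items <- unique(visits$item_id)
  p1 <- visits[visits$pass == 1L, , drop = FALSE]
  idx <- match(items, p1$item_id)
  data.frame(item_id = items,
             first_entry_ms = p1$entry_ms[idx],
             first_pass_gaze_ms = p1$gaze_ms[idx],
             stringsAsFactors = FALSE)
}

#' Item-level artifact flags
#'
#' Flags, per AOI of the presented list: `skip` (no visit at all),
#' `second_pass` (any visit beyond pass 1), `accidental_entry` (the item's
#' first visit starts within `accidental_window_ms` of trial onset and
#' before the first visit of some item earlier in reading order),
#' `blink_overlap` (a blink event intersects the pass-1 visit interval)
#' and `misarticulated` (copied from the voice annotations).
#'
#' @param visits Visits from [assign_visits()].
#' @param aois AOI rows of the list (must carry `slot` and `is_filler`).
#' @param voice Voice annotation data frame (`item_id`, `onset_ms`,
#'   `accurate`); a missing record for a non-filler item is an error.
#' @param events Event data frame (used for blink events and trial onset).
#' @param accidental_window_ms Window after trial onset within which an
#'   out-of-order entry counts as accidental (default 1000 ms).
#' @return Data frame with one row per AOI: identifiers, condition
#'   columns, and the five logical flags.
#' @export
flag_item_artifacts <- function(visits, aois, voice, events,
                                accidental_window_ms = 1000) {
  a <- aois[order(aois$slot), , drop = FALSE]
  need_voice <- a$item_id[!a$is_filler]
  miss <- setdiff(need_voice, voice$item_id)
  if (length(miss)) {
    stop("missing voice record for item(s): ", paste(miss, collapse = ", "))
  }
  trial_start <- min(events$t_start_ms)
  p1 <- visits[visits$pass == 1L, , drop = FALSE]
  first_entry <- p1$entry_ms[match(a$item_id, p1$item_id)]
  skip <- is.na(first_entry)
  second_pass <- a$item_id %in% visits$item_id[visits$pass > 1L]
  accidental <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(a))) {
    if (skip[i] || i == 1L) next
    preds <- first_entry[seq_len(i - 1L)]
    preds <- preds[!is.na(preds)]
    if (length(preds) && first_entry[i] < max(preds) &&
        first_entry[i] <= trial_start + accidental_window_ms) {
      accidental[i] <- TRUE
    }
  }
  blinks <- events[events$kind == "blink", , drop = FALSE]
  blink_overlap <- rep(FALSE, nrow(a))
  if (nrow(blinks)) {
    p1_exit <- p1$exit_ms[match(a$item_id, p1$item_id)]
    for (i in seq_len(nrow(a))) {
      if (skip[i]) next
      blink_overlap[i] <- any(blinks$t_start_ms < p1_exit[i] &
                                blinks$t_end_ms > first_entry[i])
    }
  }
  acc <- voice$accurate[match(a$item_id, voice$item_id)]
  misart <- !is.na(acc) & !acc
  data.frame(item_id = a$item_id, slot = a$slot, is_filler = a$is_filler,
             familiarity = a$familiarity, length_class = a$length_class,
             skip = skip, second_pass = second_pass,
             accidental_entry = accidental, blink_overlap = blink_overlap,
             misarticulated = misart, stringsAsFactors = FALSE)
}
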