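## Plain-text interchange formats.  Timestamps are written in ms with 3
## decimals so 1250 Hz sample boundaries (0.8 ms) stay exact.

fmt_ms <- function(x) formatC(x, format = "f", digits = 3)

#' Read and write gaze sample streams (SMI-export-like TSV)
#'
#' One trial per file; tab-separated columns `time_ms`, `x_deg`, `y_deg`,
#' `valid` (0/1).
#'
#' @param track Gaze track data frame.
#' @param path File path.
#' @return `read_gaze_tsv` returns the track data frame; `write_gaze_tsv`
#'   returns `path` invisibly.
#' @export
write_gaze_tsv <- function(track, path) {
  out <- data.frame(time_ms = fmt_ms(track$time_ms),
                    x_deg = formatC(track$x_deg, format = "f", digits = 4),
                    y_deg = formatC(track$y_deg, format = "f", digits = 4),
                    valid = as.integer(track$valid))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @export
read_gaze_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("numeric", "numeric", "numeric",
                                        "integer"))
  if (!identical(names(d), c("time_ms", "x_deg", "y_deg", "valid"))) {
    stop("malformed gaze file ", path, ": expected columns ",
         "time_ms, x_deg, y_deg, valid")
  }
  d
}

#' Read and write voice-onset annotations
#'
#' CSV dialect: columns `item_id`, `onset_ms`, `accurate` (0/1).  TextGrid
#' dialect: a Praat short TextGrid with a point tier `naming_onset` (one
#' point per item, labelled with the item id) and an interval tier
#' `accuracy` (one interval per item, label `"<item_id>:correct"` or
#' `"<item_id>:misarticulated"`); TextGrid times are in seconds.
#'
#' @param voice Data frame `item_id`, `onset_ms`, `accurate`.
#' @param path File path.
#' @param trial_end_ms End time used for the accuracy tier in TextGrid
#'   output (defaults to last onset + 1000 ms).
#' @return Readers return the voice data frame (times in ms); writers
#'   return `path` invisibly.
#' @export
write_voice_csv <- function(voice, path) {
  out <- data.frame(item_id = voice$item_id, onset_ms = fmt_ms(voice$onset_ms),
                    accurate = as.integer(voice$accurate))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_voice_csv
#' @export
read_voice_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item_id", "onset_ms", "accurate") %in% names(d))) {
    stop("malformed voice file ", path)
  }
  d$onset_ms <- as.numeric(d$onset_ms)
  d$accurate <- d$accurate != 0
  d[, c("item_id", "onset_ms", "accurate")]
}

#' @rdname write_voice_csv
#' @export
write_voice_textgrid <- function(voice, path, trial_end_ms = NULL) {
  v <- voice[order(voice$onset_ms), , drop = FALSE]
  if (is.null(trial_end_ms)) trial_end_ms <- max(v$onset_ms) + 1000
  sec <- function(ms) formatC(ms / 1000, format = "f", digits = 6)
  n <- nrow(v)
  iv_start <- c(0, v$onset_ms[-n])
  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "0",
    sec(trial_end_ms),
    "<exists>",
    "2",
    '"TextTier"',
    '"naming_onset"',
    "0",
    sec(trial_end_ms),
    as.character(n))
  for (i in seq_len(n)) {
    lines <- c(lines, sec(v$onset_ms[i]), sprintf('"%s"', v$item_id[i]))
  }
  lines <- c(lines,
             '"IntervalTier"',
             '"accuracy"',
             "0",
             sec(trial_end_ms),
             as.character(n))
  for (i in seq_len(n)) {
    lab <- sprintf('"%s:%s"', v$item_id[i],
                   if (v$accurate[i]) "correct" else "misarticulated")
    end <- if (i < n) v$onset_ms[i + 1] else trial_end_ms
    lines <- c(lines, sec(iv_start[i]), sec(end), lab)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_voice_csv
#' @export
read_voice_textgrid <- function(path) {
  lines <- readLines(path)
  unquote <- function(s) gsub('^"|"$', "", s)
  i <- which(lines == '"TextTier"')
  if (!length(i)) stop("malformed TextGrid ", path, ": no point tier")
  i <- i[1]
  tier_name <- unquote(lines[i + 1])
  np <- as.integer(lines[i + 4])
  onset_ms <- numeric(np); item_id <- character(np)
  for (k in seq_len(np)) {
    onset_ms[k] <- as.numeric(lines[i + 4 + 2 * k - 1]) * 1000
    item_id[k] <- unquote(lines[i + 4 + 2 * k])
  }
  j <- which(lines == '"IntervalTier"')
  accurate <- rep(TRUE, np)
  if (length(j)) {
    j <- j[1]
    ni <- as.integer(lines[j + 4])
    for (k in seq_len(ni)) {
      lab <- unquote(lines[j + 4 + 3 * k])
      parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
      if (length(parts) == 2L) {
        accurate[match(parts[1], item_id)] <- parts[2] == "correct"
      }
    }
  }
  data.frame(item_id = item_id, onset_ms = onset_ms, accurate = accurate,
             stringsAsFactors = FALSE)
}

#' Read and write AOI/stimulus-list definitions (CSV)
#'
#' @param stimuli An `evs_stimuli` data frame.
#' @param path File path.
#' @return The reader returns an `evs_stimuli` data frame; the writer
#'   returns `path` invisibly.
#' @export
write_aoi_csv <- function(stimuli, path) {
  utils::write.csv(as.data.frame(stimuli), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_aoi_csv
#' @export
read_aoi_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("list_id", "item_id", "row", "col", "slot", "x0", "y0", "x1",
            "y1", "familiarity", "length_class", "regularity", "is_filler")
  if (!all(need %in% names(d))) stop("malformed AOI file ", path)
  d$is_filler <- as.logical(d$is_filler)
  class(d) <- c("evs_stimuli", "data.frame")
  d
}

#' Generic CSV helpers for pipeline artifacts
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return The reader returns a data frame; the writer returns `path`
#'   invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
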