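#' Build homogeneous grid stimulus lists
#'
#' Partitions the experimental items of every familiarity x length x
#' regularity cell into lists that are homogeneous in all three factors,
#' lays each list out on a row-major grid of rectangular AOIs, and flags
#' filler positions: every first-column AOI and the final AOI of the
#' reading order.  Long-item lists use the long grid (default 3x4, 12
#' AOIs), short-item lists the short grid (default 3x5, 15 AOIs).
#'
#' A long list therefore holds `rows*cols - rows - 1` experimental items
#' (8 by default) and a short list 11.  When a cell's item count does not
#' divide the per-list capacity, `filler_policy = "pad"` (default) turns
#' the trailing experimental-eligible slots of the cell's last list into
#' additional fillers, keeping every experimental item exactly once;
#' `"strict"` raises an error naming the cell.  Under the default design
#' (40 items per cell, 30 regular + 10 irregular) padding produces 30
#' lists and 156 fillers in total.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `evs_stimuli`: a data frame with one row per
#'   AOI and columns `list_id`, `item_id`, `row`, `col`, `slot` (reading
#'   order within the list), `x0`, `y0`, `x1`, `y1` (degrees),
#'   `familiarity`, `length_class`, `regularity`, `is_filler`.
#' @examples
#' stim <- build_stimulus_lists(sim_config())
#' sum(!stim$is_filler)  # 240 experimental items under the default design
#' @export
build_stimulus_lists <- function(config = sim_config()) {
  grid <- config$grid
  cells <- expand.grid(
    familiarity = c("HF", "LF", "PW"),
    length_class = c("long", "short"),
    regularity = c("regular", "irregular"),
    stringsAsFactors = FALSE
  )
  n_irregular <- config$items_per_cell - config$regular_per_cell
  out <- vector("list", nrow(cells))
  list_counter <- 0L
  for (ci in seq_len(nrow(cells))) {
    fam <- cells$familiarity[ci]
    len <- cells$length_class[ci]
    reg <- cells$regularity[ci]
    n_items <- if (reg == "regular") config$regular_per_cell else n_irregular
    if (n_items == 0L) next
    rows <- if (len == "long") grid$rows_long else grid$rows_short
    cols <- if (len == "long") grid$cols_long else grid$cols_short
    capacity <- rows * cols - rows - 1L  # minus first column and last slot
    if (capacity <= 0L) {
      stop("list grid ", rows, "x", cols, " leaves no experimental slots")
    }
    if (config$filler_policy == "strict" && n_items %% capacity != 0L) {
      stop(sprintf(
        "cell %s/%s/%s: %d items are not partitionable into lists of %d experimental slots",
        fam, len, reg, n_items, capacity))
    }
    n_lists <- ceiling(n_items / capacity)
    ids <- sprintf("%s_%s_%s_%03d", fam, len, substr(reg, 1, 3),
                   seq_len(n_items))
    assigned <- 0L
    for (li in seq_len(n_lists)) {
      list_counter <- list_counter + 1L
      list_id <- sprintf("L%02d", list_counter)
      aois <- aoi_grid(rows, cols, config$geometry)
      aois$list_id <- list_id
      aois$familiarity <- fam
      aois$length_class <- len
      aois$regularity <- reg
      aois$is_filler <- aois$col == 1L | aois$slot == rows * cols
      exp_slots <- which(!aois$is_filler)
      take <- min(length(exp_slots), n_items - assigned)
      aois$item_id <- sprintf("fil_%s_%02d", list_id, aois$slot)
      if (take > 0L) {
        aois$item_id[exp_slots[seq_len(take)]] <- ids[assigned + seq_len(take)]
      }
      if (take < length(exp_slots)) {
        # pad leftover experimental-eligible slots with fillers
        aois$is_filler[exp_slots[setdiff(seq_along(exp_slots), seq_len(take))]] <- TRUE
      }
      assigned <- assigned + take
      out[[length(out) + 1L]] <- aois
    }
    stopifnot(assigned == n_items)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- empty_stimuli()
  }
  rownames(out) <- NULL
  out <- out[, c("list_id", "item_id", "row", "col", "slot",
                 "x0", "y0", "x1", "y1",
                 "familiarity", "length_class", "regularity", "is_filler")]
  class(out) <- c("evs_stimuli", "data.frame")
  check_aoi_spacing(out, config$geometry$min_spacing)
  out
}

empty_stimuli <- function() {
  data.frame(list_id = character(), item_id = character(),
             row = integer(), col = integer(), slot = integer(),
             x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
             familiarity = character(), length_class = character(),
             regularity = character(), is_filler = logical(),
             stringsAsFactors = FALSE)
}

# Row-major AOI grid; horizontal neighbours are separated by exactly the
# configured minimum spacing, rows by row_gap.
aoi_grid <- function(rows, cols, geometry) {
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  g <- g[order(g$row, g$col), , drop = FALSE]
  g$slot <- seq_len(nrow(g))
  pitch_x <- geometry$aoi_width + geometry$min_spacing
  pitch_y <- geometry$aoi_height + geometry$row_gap
  g$x0 <- geometry$origin_x + (g$col - 1L) * pitch_x
  g$x1 <- g$x0 + geometry$aoi_width
  g$y0 <- geometry$origin_y + (g$row - 1L) * pitch_y
  g$y1 <- g$y0 + geometry$aoi_height
  g$item_id <- NA_character_
  g
}

check_aoi_spacing <- function(aois, min_spacing) {
  for (lid in unique(aois$list_id)) {
    a <- aois[aois$list_id == lid, ]
    for (r in unique(a$row)) {
      row_aois <- a[a$row == r, ]
      row_aois <- row_aois[order(row_aois$x0), ]
      if (nrow(row_aois) > 1L) {
        gaps <- row_aois$x0[-1L] - row_aois$x1[-nrow(row_aois)]
        if (any(gaps < min_spacing - 1e-9)) {
          stop("AOI spacing below configured minimum in list ", lid)
        }
      }
    }
  }
  invisible(TRUE)
}

aoi_centers <- function(aois) {
  data.frame(item_id = aois$item_id,
             x = (aois$x0 + aois$x1) / 2,
             y = (aois$y0 + aois$y1) / 2,
             stringsAsFactors = FALSE)
}
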