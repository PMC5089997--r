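# artifact-free configuration used by round-trip and recovery tests;
# named overrides in ... win over the zeroed artifact rates
clean_config <- function(seed = 1, ...) {
  args <- list(seed = seed, blink_rate = 0, skip_rate = 0,
               regression_rate = 0, misarticulation_rate = 0,
               accidental_entry_rate = 0, signal_loss_rate = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# one-list stimuli for a given cell, via the exported builder
one_list <- function(config, familiarity = "HF", length_class = "short",
                     list_id = NULL) {
  stim <- build_stimulus_lists(config)
  sel <- stim$familiarity == familiarity & stim$length_class == length_class
  lid <- if (is.null(list_id)) stim$list_id[sel][1] else list_id
  stim[stim$list_id == lid, , drop = FALSE]
}

# constant-duration gaze track helper (stationary fixation)
flat_track <- function(n, x = 1, y = 1, rate = 1250, valid = 1) {
  data.frame(time_ms = (seq_len(n) - 1) * 1000 / rate,
             x_deg = x, y_deg = y, valid = valid)
}
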