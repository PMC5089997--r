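test_that("degenerate timing draws hit the configured values exactly", {
  cond <- default_conditions()
  cond$offset_sd <- 0
  cond$gaze_sd <- 0
  cfg <- sim_config(conditions = cond)
  set.seed(1)
  d <- simulate_item_timing("HF", "short", cfg, n = 20)
  expect_equal(d$offset_evs_ms, rep(258.9, 20))
  expect_equal(d$gaze_ms, rep(cond$gaze_mean[cond$familiarity == "HF" &
                                               cond$length_class == "short"],
                              20))
  # ratio mode with R fixed at 1 puts every item exactly on the boundary
  cond2 <- default_conditions()
  cond2$gtpt_mean <- 1
  cond2$gtpt_sd <- 0
  cfg2 <- sim_config(mode = "ratio", conditions = cond2)
  set.seed(1)
  d2 <- simulate_item_timing("LF", "long", cfg2, n = 20)
  expect_equal(d2$offset_evs_ms, rep(0, 20))
  expect_equal(d2$gt_pt, rep(1, 20))
})

test_that("unknown condition is rejected", {
  expect_error(simulate_item_timing("XX", "short", sim_config()),
               "unknown condition")
})

test_that("Monte-Carlo mean of offset draws matches closed-form SE bound", {
  cfg <- sim_config()
  set.seed(42)
  n <- 1e5
  # HF-short: virtually no truncation, so the sample mean must match the
  # generating mean within 3 closed-form standard errors
  d <- simulate_item_timing("HF", "short", cfg, n = n)
  expect_lt(abs(mean(d$offset_evs_ms) - 258.9), 3 * 134.8 / sqrt(n))
  # PW-long: truncation at onset EVS > 0 is active; the calibrated
  # sampler must still return the configured marginal moments
  d2 <- simulate_item_timing("PW", "long", cfg, n = n)
  expect_lt(abs(mean(d2$offset_evs_ms) - (-63.1)), 3 * 185 / sqrt(n))
  expect_lt(abs(sd(d2$offset_evs_ms) - 185) / 185, 0.02)
  expect_true(all(d2$onset_evs_ms > 0))
})

test_that("ratio-mode draws respect positivity and match configured moments", {
  cfg <- sim_config(mode = "ratio")
  set.seed(43)
  n <- 1e5
  d <- simulate_item_timing("PW", "long", cfg, n = n)
  expect_true(all(d$onset_evs_ms > 0))
  expect_true(all(d$gaze_ms >= cfg$min_gaze_ms))
  expect_lt(abs(mean(d$gt_pt) - 1.15), 3 * 0.36 / sqrt(n) + 0.005)
})

test_that("noiseless trial realizes ground truth exactly", {
  cond <- default_conditions()
  cond$offset_sd <- 0
  cond$gaze_sd <- 0
  cfg <- sim_config(conditions = cond, blink_rate = 0, skip_rate = 0,
                    regression_rate = 0, misarticulation_rate = 0,
                    accidental_entry_rate = 0, signal_loss_rate = 0,
                    fixation_jitter_sd = 0)
  stim <- build_stimulus_lists(cfg)
  a <- stim[stim$list_id == "L01", ]
  set.seed(5)
  tr <- simulate_trial(a, cfg)
  gm <- cond$gaze_mean[cond$familiarity == a$familiarity[1] &
                         cond$length_class == a$length_class[1]]
  # realized gaze quantized to the 0.8 ms grid
  expect_true(all(abs(tr$truth$gaze_ms - gm) <= cfg$dt_ms / 2 + 1e-9))
  # ground-truth identity: offset = (voice - entry) - gaze, exactly
  expect_equal(tr$truth$offset_evs_ms,
               tr$truth$voice_onset_ms - tr$truth$first_entry_ms -
                 tr$truth$gaze_ms)
  # exactly one fixation run per AOI (plus start and end fixations)
  ev <- detect_events(tr$track)
  expect_equal(sum(ev$kind == "fixation"), nrow(a) + 2L)
})

test_that("saturated regression rate gives every non-final item a second pass", {
  cfg <- clean_config(seed = 6, regression_rate = 1)
  a <- one_list(cfg, "HF", "long")
  set.seed(6)
  tr <- simulate_trial(a, cfg)
  expect_true(all(tr$truth$second_pass[-nrow(tr$truth)]))
  expect_false(tr$truth$second_pass[nrow(tr$truth)])
})

test_that("identical config and seed give bit-identical trials", {
  cfg <- sim_config(seed = 9)
  stim <- build_stimulus_lists(cfg)
  a <- stim[stim$list_id == "L05", ]
  set.seed(9); t1 <- simulate_trial(a, cfg)
  set.seed(9); t2 <- simulate_trial(a, cfg)
  expect_identical(t1, t2)
  e1 <- simulate_experiment(sim_config(seed = 10, items_per_cell = 8,
                                       regular_per_cell = 8),
                            n_subjects = 1, lists = "L01")
  e2 <- simulate_experiment(sim_config(seed = 10, items_per_cell = 8,
                                       regular_per_cell = 8),
                            n_subjects = 1, lists = "L01")
  expect_identical(e1$trials, e2$trials)
})

test_that("lmm dataset with zero variances reproduces cell means exactly", {
  d <- simulate_lmm_dataset(variances = c(item = 0, subject = 0, residual = 0),
                            coding = "full", n_subjects = 3,
                            n_items_per_cell = 2, seed = 1)
  cell <- function(fam, len) unique(d$response[d$familiarity == fam &
                                                 d$length_class == len])
  expect_equal(cell("HF", "long"), 191.4)
  expect_equal(cell("LF", "long"), 191.4 - 80.77)
  expect_equal(cell("HF", "short"), 191.4 + 134.80)
  expect_equal(cell("PW", "short"), 191.4 - 202.20 + 134.80 + 130.53)
  # noise off: LF - HF difference of generated cell means is the beta
  expect_equal(cell("LF", "long") - cell("HF", "long"), -80.77)
})

test_that("lmm dataset variance decomposes as the sum of components", {
  vars <- c(item = 8323, subject = 6093, residual = 16684)
  d <- simulate_lmm_dataset(variances = vars, coding = "main", seed = 2)
  # brute-force pooled within-cell variance against the theoretical total
  total <- sum(vars)
  cells <- split(d$response, paste(d$familiarity, d$length_class))
  pooled <- sum(vapply(cells, function(v) sum((v - mean(v))^2), numeric(1))) /
    (nrow(d) - length(cells))
  expect_lt(abs(pooled - total) / total, 0.15)
})

test_that("negative variances are rejected", {
  expect_error(simulate_lmm_dataset(variances = c(item = -1, subject = 0,
                                                  residual = 1)),
               "variances")
})

test_that("reading velocity follows the configured linear model", {
  s <- data.frame(subject_id = c("a", "b", "c"),
                  mean_offset_evs = c(100, 200, 300))
  set.seed(1)
  v0 <- simulate_reading_velocity(s, slope = 0, intercept = 40, noise_sd = 0)
  expect_equal(v0$velocity, rep(40, 3))
  v1 <- simulate_reading_velocity(s, slope = 0.1, intercept = 40,
                                  noise_sd = 0)
  expect_equal(v1$velocity, c(50, 60, 70))
  expect_true(all(diff(v1$velocity[order(s$mean_offset_evs)]) > 0))
  # cap at the concurrent test's item count
  v2 <- simulate_reading_velocity(s, slope = 1, intercept = 40, noise_sd = 0)
  expect_true(all(v2$velocity <= 75))
})
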