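measure_row <- function(entry, gaze, onset) {
  flags <- data.frame(item_id = "w1", slot = 2L, is_filler = FALSE,
                      familiarity = "HF", length_class = "short",
                      skip = FALSE, second_pass = FALSE,
                      accidental_entry = FALSE, blink_overlap = FALSE,
                      misarticulated = FALSE, stringsAsFactors = FALSE)
  fp <- data.frame(item_id = "w1", first_entry_ms = entry,
                   first_pass_gaze_ms = gaze, stringsAsFactors = FALSE)
  voice <- data.frame(item_id = "w1", onset_ms = onset, accurate = TRUE,
                      stringsAsFactors = FALSE)
  compute_measures(flags, fp, voice)
}

test_that("span algebra holds on canonical magnitudes", {
  m <- measure_row(entry = 1000, gaze = 494, onset = 1642)
  expect_equal(m$onset_evs_ms, 642)
  expect_equal(m$offset_evs_ms, 148)
  expect_equal(m$gt_pt, 494 / 642, tolerance = 1e-12)
  expect_equal(m$span_class, "eye_voice")
})

test_that("voice at fixation offset is the boundary case", {
  m <- measure_row(entry = 500, gaze = 400, onset = 900)
  expect_equal(m$offset_evs_ms, 0)
  expect_equal(m$gt_pt, 1)
  expect_equal(m$span_class, "boundary")
})

test_that("negative offset EVS yields GT/PT above one (voice-eye span)", {
  # offset -63.1 with onset 420: gaze = 483.1, GT/PT = 483.1/420
  m <- measure_row(entry = 0, gaze = 483.1, onset = 420)
  expect_equal(m$offset_evs_ms, -63.1, tolerance = 1e-9)
  expect_equal(m$gt_pt, 483.1 / 420, tolerance = 1e-12)
  expect_equal(round(m$gt_pt, 2), 1.15)
  expect_equal(m$span_class, "voice_eye")
  # identity: gt_pt = 1 - offset/onset
  expect_equal(m$gt_pt, 1 - m$offset_evs_ms / m$onset_evs_ms,
               tolerance = 1e-12)
})

test_that("voice onset before first entry flags an invalid record", {
  m <- measure_row(entry = 1000, gaze = 200, onset = 900)
  expect_true(m$invalid_onset)
  expect_true(is.na(m$gt_pt))
})

test_that("identities and sign equivalence hold on full pipeline output", {
  set.seed(70)
  cfg <- clean_config(seed = 70)
  exp <- simulate_condition_stream("PW", "long", cfg, n_items = 120)
  an <- analyze_experiment(exp)
  m <- an$measures
  expect_equal(m$onset_evs_ms, m$voice_onset_ms - m$first_entry_ms)
  expect_equal(m$offset_evs_ms, m$onset_evs_ms - m$first_pass_gaze_ms)
  pos <- !is.na(m$onset_evs_ms) & m$onset_evs_ms > 0
  expect_equal(m$gt_pt[pos], m$first_pass_gaze_ms[pos] / m$onset_evs_ms[pos])
  # gt_pt > 1  <=>  offset < 0 whenever onset EVS > 0
  expect_equal(m$gt_pt[pos] > 1, m$offset_evs_ms[pos] < 0)
  expect_equal(sign(m$offset_evs_ms[pos]), sign(1 - m$gt_pt[pos]))
})

test_that("crossing percentile follows the integer-quantile scan", {
  expect_equal(crossing_percentile(c(5, 10, 20), "offset"), 100L)
  vals <- c(-(5:1), seq_len(95))   # 5% negative
  got <- crossing_percentile(vals, "offset")
  # brute-force reference scan over integer percentiles
  brute <- 100L
  for (p in 1:100) {
    if (quantile(vals, p / 100, type = 7) < 0) { brute <- p; break }
  }
  expect_equal(got, brute)
  expect_lte(got, 10L)
  expect_error(crossing_percentile(numeric(0), "offset"), "empty")
  # gtpt direction
  expect_equal(crossing_percentile(c(0.2, 0.4, 0.9), "gtpt"), 100L)
  g <- c(rep(0.5, 90), rep(1.5, 10))
  bruteg <- 100L
  for (p in 1:100) {
    if (quantile(g, p / 100, type = 7) > 1) { bruteg <- p; break }
  }
  expect_equal(crossing_percentile(g, "gtpt"), bruteg)
})

test_that("GT/PT crossing percentiles order PW-long below HF-short", {
  # synthetic Gaussian condition data at the reported means/SDs
  set.seed(71)
  hf_short <- rnorm(5000, 0.59, 0.18)
  pw_long <- rnorm(5000, 1.15, 0.36)
  expect_lt(crossing_percentile(pw_long, "gtpt"),
            crossing_percentile(hf_short, "gtpt"))
})

test_that("condition summary reports moments, crossings and motor flag", {
  set.seed(72)
  n <- 400
  mk <- function(fam, len, off_mean, gt_mean) {
    data.frame(subject_id = "S01", list_id = "L01",
               item_id = sprintf("%s_%s_%d", fam, len, 1:n),
               familiarity = fam, length_class = len,
               offset_evs_ms = rnorm(n, off_mean, 50),
               gt_pt = rnorm(n, gt_mean, 0.1), stringsAsFactors = FALSE)
  }
  meas <- rbind(mk("HF", "short", 258.9, 0.59), mk("PW", "long", -63.1, 1.15))
  s <- summarize_conditions(meas)
  hf <- s[s$familiarity == "HF", ]
  pw <- s[s$familiarity == "PW", ]
  expect_lt(abs(hf$mean_offset_evs - 258.9), 3 * 50 / sqrt(n))
  expect_true(hf$exceeds_motor_reference)   # 258.9 > 150
  expect_false(pw$exceeds_motor_reference)  # negative mean
  expect_equal(pw$span_class, "voice_eye")
  expect_equal(hf$span_class, "eye_voice")
  # mean 122.7 does not exceed the 150 ms motor reference
  m3 <- rbind(mk("PW", "short", 122.7, 0.82), mk("HF", "long", 191.4, 0.71))
  s3 <- summarize_conditions(m3)
  expect_false(s3$exceeds_motor_reference[s3$familiarity == "PW"])
  expect_true(s3$exceeds_motor_reference[s3$familiarity == "HF"])
})

test_that("condition summary is permutation invariant and exact at SD 0", {
  meas <- data.frame(subject_id = "S01", list_id = "L01",
                     item_id = sprintf("w%d", 1:10),
                     familiarity = "LF", length_class = "short",
                     offset_evs_ms = rep(210.2, 10),
                     gt_pt = rep(0.68, 10), stringsAsFactors = FALSE)
  s <- summarize_conditions(meas)
  expect_equal(s$sd_offset_evs, 0)
  set.seed(73)
  meas2 <- meas[sample(nrow(meas)), ]
  meas2$offset_evs_ms <- meas2$offset_evs_ms + rnorm(10)
  s2a <- summarize_conditions(meas2)
  s2b <- summarize_conditions(meas2[sample(nrow(meas2)), ])
  expect_equal(s2a, s2b)
})

test_that("summary errors on near-empty conditions", {
  meas <- data.frame(subject_id = "S01", list_id = "L01", item_id = "w1",
                     familiarity = "HF", length_class = "short",
                     offset_evs_ms = 100, gt_pt = 0.5,
                     stringsAsFactors = FALSE)
  expect_error(summarize_conditions(meas), "fewer than 2")
})
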