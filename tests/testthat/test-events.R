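test_that("velocity is zero for stationary gaze and exact for a ramp", {
  tr <- flat_track(200)
  expect_equal(compute_velocity(tr), rep(0, 200))
  # 30 degrees over 1 s at 1250 Hz: constant 30 deg/s at interior samples
  n <- 1250
  ramp <- data.frame(time_ms = (seq_len(n) - 1) * 0.8,
                     x_deg = seq(0, 30, length.out = n), y_deg = 0,
                     valid = 1)
  v <- compute_velocity(ramp)
  expect_true(all(abs(v - 30 / (1 - 1 / n)) < 0.1))
})

test_that("velocity matches an analytic derivative on a smooth saccade", {
  # raised-cosine position profile: x(t) = A/2 (1 - cos(pi t / T)),
  # velocity = A pi / (2T) sin(pi t / T)
  A <- 10; T_ms <- 64; dt <- 0.8
  t <- seq(0, T_ms, by = dt)
  tr <- data.frame(time_ms = t, x_deg = A / 2 * (1 - cos(pi * t / T_ms)),
                   y_deg = 0, valid = 1)
  v <- compute_velocity(tr, window = 5)
  v_true <- A * pi / (2 * T_ms) * sin(pi * t / T_ms) * 1000
  interior <- t > 10 & t < T_ms - 10
  expect_true(all(abs(v[interior] - v_true[interior]) / v_true[interior] < 0.05))
  # brute-force oracle: central finite difference at 10x oversampling
  fine_dt <- dt / 10
  xfun <- function(tt) A / 2 * (1 - cos(pi * tt / T_ms))
  v_fd <- (xfun(t + fine_dt) - xfun(t - fine_dt)) / (2 * fine_dt) * 1000
  expect_true(all(abs(v[interior] - v_fd[interior]) / v_fd[interior] < 0.05))
})

test_that("velocity errors on too-short tracks", {
  expect_error(compute_velocity(flat_track(4), window = 5), "shorter")
})

test_that("sub-minimum fixations are discarded, not merged", {
  dt <- 0.8
  n1 <- 250; ns <- 30; n2 <- 50; n3 <- 250  # 200ms fix, saccade, 40ms fix, 200ms fix
  x <- c(rep(0, n1), seq(0, 8, length.out = ns), rep(8, n2),
         seq(8, 16, length.out = ns), rep(16, n3))
  tr <- data.frame(time_ms = (seq_along(x) - 1) * dt, x_deg = x, y_deg = 0,
                   valid = 1)
  ev <- detect_events(tr)
  disc <- ev[ev$kind == "discarded", ]
  expect_equal(nrow(disc), 1L)
  expect_lt(disc$t_end_ms - disc$t_start_ms, 50)
  expect_equal(sum(ev$kind == "fixation"), 2L)
})

test_that("event boundaries match a brute-force sample-by-sample scan", {
  # independent reference: classify each sample by thresholding the same
  # velocity series in an explicit loop, then compare run boundaries
  brute_events <- function(track, vthr = 30) {
    v <- compute_velocity(track)
    lab <- character(nrow(track))
    for (i in seq_len(nrow(track))) {
      lab[i] <- if (track$valid[i] == 0) "invalid"
                else if (v[i] > vthr) "saccade" else "still"
    }
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    data.frame(kind = r$values, start = ends - r$lengths + 1L, end = ends)
  }
  set.seed(31)
  for (rep in 1:20) {
    cfg <- clean_config(seed = rep, fixation_jitter_sd = 0.05)
    a <- one_list(cfg, sample(c("HF", "LF", "PW"), 1),
                  sample(c("short", "long"), 1))
    tr <- simulate_trial(a, cfg)
    # perturb validity to exercise blink handling
    if (rep %% 3 == 0) tr$track$valid[500:700] <- 0
    ev <- detect_events(tr$track)
    ref <- brute_events(tr$track)
    ref$kind[ref$kind == "still"] <- "fix_or_discarded"
    got_runs <- data.frame(
      kind = ifelse(ev$kind %in% c("fixation", "discarded"),
                    "fix_or_discarded",
                    ifelse(ev$kind %in% c("blink", "lost"), "invalid",
                           ev$kind)),
      start = round(ev$t_start_ms / 0.8) + 1,
      end = round(ev$t_end_ms / 0.8))
    expect_equal(got_runs$kind, ref$kind)
    expect_equal(got_runs$start, ref$start)
    expect_equal(got_runs$end, ref$end)
  }
})

test_that("event durations partition the track duration exactly", {
  set.seed(32)
  cfg <- clean_config(seed = 32, blink_rate = 0.3, regression_rate = 0.2)
  a <- one_list(cfg, "LF", "long")
  tr <- simulate_trial(a, cfg)
  ev <- detect_events(tr$track)
  total <- nrow(tr$track) * cfg$dt_ms
  expect_equal(sum(ev$t_end_ms - ev$t_start_ms), total)
  # events are ordered and non-overlapping
  expect_true(all(diff(ev$t_start_ms) > 0))
  expect_true(all(ev$t_start_ms[-1] == ev$t_end_ms[-nrow(ev)]))
})

test_that("raising the minimum fixation never increases retained fixations", {
  set.seed(33)
  cfg <- clean_config(seed = 33, fixation_jitter_sd = 0.08)
  a <- one_list(cfg, "HF", "short")
  tr <- simulate_trial(a, cfg)
  counts <- vapply(c(10, 30, 50, 80, 120), function(mf) {
    sum(detect_events(tr$track, min_fixation_ms = mf)$kind == "fixation")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("an all-invalid track yields a single lost event", {
  tr <- flat_track(100, valid = 0)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "lost")
  expect_true(isTRUE(attr(ev, "all_lost")))
})

test_that("blink versus lost depends on duration and bracketing", {
  tr <- flat_track(2000)
  tr$valid[300:500] <- 0          # 160 ms, bracketed -> blink
  tr$valid[1000:1900] <- 0        # 720 ms -> lost
  kinds <- detect_events(tr)$kind
  expect_true("blink" %in% kinds)
  expect_true("lost" %in% kinds)
})

test_that("contamination thresholds are strict inequalities", {
  st <- data.frame(subject_id = "S01", trial_id = c("a", "b"),
                   invalid_frac = c(0.30, 0.25))
  fl <- flag_contamination(st)
  expect_equal(fl$trials$contaminated, c(TRUE, FALSE))
  # 9/30 contaminated trials (30%) excludes a subject; 7/30 (23%) does not
  st2 <- rbind(
    data.frame(subject_id = "S_bad", trial_id = sprintf("t%02d", 1:30),
               invalid_frac = c(rep(0.5, 9), rep(0, 21))),
    data.frame(subject_id = "S_ok", trial_id = sprintf("t%02d", 1:30),
               invalid_frac = c(rep(0.5, 7), rep(0, 23))))
  fl2 <- flag_contamination(st2)
  expect_equal(fl2$subjects$excluded[fl2$subjects$subject_id == "S_bad"], TRUE)
  expect_equal(fl2$subjects$excluded[fl2$subjects$subject_id == "S_ok"], FALSE)
})
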