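lmm_formula <- function(rhs) {
  as.formula(paste("response ~", rhs, "+ (1 | subject_id) + (1 | item_id)"))
}

test_that("with zero generating variances the fit collapses to OLS", {
  d <- simulate_lmm_dataset(variances = c(item = 0, subject = 0,
                                          residual = 100),
                            n_subjects = 8, n_items_per_cell = 4, seed = 1)
  fit <- suppressMessages(fit_evs_lmm(lmm_formula("familiarity + length_class"), d))
  ols <- lm(response ~ familiarity + length_class, data = d)
  expect_equal(coef(fit), coef(ols), tolerance = 1e-6)
})

test_that("balanced two-condition contrast equals the cell-mean difference", {
  d <- simulate_lmm_dataset(variances = c(item = 0, subject = 0,
                                          residual = 400),
                            n_subjects = 6, n_items_per_cell = 6, seed = 2)
  d <- d[d$familiarity %in% c("HF", "LF") & d$length_class == "long", ]
  d$familiarity <- droplevels(d$familiarity)
  fit <- suppressMessages(fit_evs_lmm(lmm_formula("familiarity"), d))
  closed_form <- mean(d$response[d$familiarity == "LF"]) -
    mean(d$response[d$familiarity == "HF"])
  expect_equal(unname(coef(fit)["familiarityLF"]), closed_form,
               tolerance = 1e-6)
})

test_that("fit recovers the generating fixed effects and variances", {
  d <- simulate_lmm_dataset(coding = "main", seed = 3)
  fit <- fit_evs_lmm(lmm_formula("familiarity + length_class"), d)
  est <- coef(fit)
  # within 2 printed SEs of the generating coefficients
  expect_lt(abs(est[["familiarityLF"]] - (-80.77)), 2 * 14.91)
  expect_lt(abs(est[["familiarityPW"]] - (-202.20)), 2 * 15.00)
  expect_lt(abs(est[["length_classshort"]] - 134.80), 2 * 13.76)
  expect_lt(abs(fit$varcomp[["residual"]] - 16684) / 16684, 0.10)
  d2 <- simulate_lmm_dataset(coding = "full", seed = 4)
  fit2 <- fit_evs_lmm(lmm_formula("familiarity * length_class"), d2)
  expect_lt(abs(coef(fit2)[["familiarityPW:length_classshort"]] - 130.53),
            2 * 19.27)
})

test_that("ML invariance under shift and scale of the response", {
  d <- simulate_lmm_dataset(n_subjects = 6, n_items_per_cell = 3, seed = 5)
  f0 <- fit_evs_lmm(lmm_formula("familiarity"), d)
  d_shift <- d; d_shift$response <- d$response + 100
  f_shift <- fit_evs_lmm(lmm_formula("familiarity"), d_shift)
  expect_equal(coef(f_shift)[["(Intercept)"]],
               coef(f0)[["(Intercept)"]] + 100, tolerance = 1e-4)
  expect_equal(coef(f_shift)[["familiarityLF"]], coef(f0)[["familiarityLF"]],
               tolerance = 1e-4)
  d_scale <- d; d_scale$response <- d$response * 2
  f_scale <- fit_evs_lmm(lmm_formula("familiarity"), d_scale)
  expect_equal(coef(f_scale), coef(f0) * 2, tolerance = 1e-3)
  expect_equal(f_scale$varcomp[["residual"]],
               f0$varcomp[["residual"]] * 4, tolerance = 1e-2)
})

test_that("singular designs and bad inputs error informatively", {
  d <- simulate_lmm_dataset(n_subjects = 4, n_items_per_cell = 2, seed = 6)
  d$dup <- as.numeric(d$length_class == "short")
  expect_error(
    fit_evs_lmm(response ~ length_class + dup + (1 | subject_id) +
                  (1 | item_id), d),
    "aliased")
  d2 <- d; d2$response[1] <- NA
  expect_error(fit_evs_lmm(lmm_formula("familiarity"), d2))
})

test_that("identical fits give a zero LRT and df follows the ladder", {
  d <- simulate_lmm_dataset(n_subjects = 8, n_items_per_cell = 4, seed = 7)
  lad <- evs_lrt_ladder(d, "response")
  expect_equal(lad$tests$df, c(2, 1, 2))
  f <- lad$fits$additive
  same <- lrt(f, f)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_error(lrt(lad$fits$intercept, lad$fits$additive), "fewer")
})

test_that("nested OLS LRT equals the closed-form RSS expression", {
  set.seed(8)
  n <- 50
  x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
  full <- lm(y ~ x); reduced <- lm(y ~ 1)
  got <- lrt(full, reduced)
  rss_f <- sum(resid(full)^2); rss_r <- sum(resid(reduced)^2)
  expect_equal(got$chi2, n * log(rss_r / rss_f), tolerance = 1e-8)
  expect_equal(got$df, 1)
})

test_that("|t| > 2 significance rule is strict", {
  fit <- list(fixed = data.frame(term = c("a", "b", "c", "d"),
                                 estimate = 1, se = 1,
                                 t = c(-5.42, 2.0, 1.99, 2.01)))
  expect_equal(unname(significance_by_t(fit)), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("velocity regression recovers a noiseless slope with tiny p", {
  s <- data.frame(subject_id = sprintf("S%02d", 1:20),
                  mean_offset_evs = seq(50, 300, length.out = 20))
  set.seed(9)
  s <- simulate_reading_velocity(s, slope = 0.08, intercept = 35,
                                 noise_sd = 0)
  vr <- velocity_regression(s)
  expect_equal(vr$slope, 0.08, tolerance = 1e-8)
  expect_lt(vr$lrt$p, 1e-6)
  expect_equal(vr$lrt$df, 1)
  s$mean_offset_evs <- 100
  expect_error(velocity_regression(s), "constant")
})

test_that("null-slope LRT rejects at about the nominal 5% level", {
  set.seed(10)
  n_rep <- 1000; n_subj <- 30
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    s <- data.frame(subject_id = seq_len(n_subj),
                    mean_offset_evs = rnorm(n_subj, 150, 60))
    s <- simulate_reading_velocity(s, slope = 0, intercept = 40,
                                   noise_sd = 5, max_score = Inf)
    if (velocity_regression(s)$lrt$p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  # chi2(1) reference is asymptotic; allow 3 binomial SEs + small-n excess
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.015)
})

test_that("interaction LRT is chi-squared calibrated under the null", {
  set.seed(11)
  n_rep <- 120
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    d <- simulate_lmm_dataset(coding = "main",
                              variances = c(item = 2000, subject = 2000,
                                            residual = 8000),
                              n_subjects = 8, n_items_per_cell = 5)
    full <- suppressMessages(
      fit_evs_lmm(lmm_formula("familiarity * length_class"), d))
    add <- suppressMessages(
      fit_evs_lmm(lmm_formula("familiarity + length_class"), d))
    if (lrt(full, add)$p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.02)
})
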