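#' Fit a crossed random-intercepts model by maximum likelihood
#'
#' Gaussian linear mixed model with fixed condition effects and crossed
#' random intercepts for subjects and items, estimated by ordinary ML
#' (not REML) so that nested fits can be compared with likelihood-ratio
#' tests.  Treatment contrasts with HF and long as reference levels are
#' the conventional coding, giving coefficients interpretable as LF-HF,
#' PW-HF and short-long differences.
#'
#' @param formula An lme4-style formula, e.g.
#'   `offset_evs_ms ~ familiarity * length_class + (1 | subject_id) + (1 | item_id)`.
#' @param data Data frame with the response, condition factors and
#'   grouping identifiers; grouping columns are coerced to factors.
#' @param ... Passed to [lme4::lmer()].
#' @return Object of class `evs_lmm`: list with `fixed` (data frame
#'   `term`, `estimate`, `se`, `t`), `varcomp` (named variances: one per
#'   grouping factor plus `residual`), `loglik`, `df` (fitted parameter
#'   count), `nobs`, `formula` and the underlying `model`.
#' @examples
#' d <- simulate_lmm_dataset(n_subjects = 6, n_items_per_cell = 4, seed = 1)
#' fit <- fit_evs_lmm(
#'   response ~ familiarity + length_class + (1 | subject_id) + (1 | item_id),
#'   d)
#' fit$fixed
#' @export
fit_evs_lmm <- function(formula, data, ...) {
  fixed_form <- lme4::nobars(formula)
  resp <- stats::model.response(
    stats::model.frame(fixed_form, data, na.action = stats::na.pass))
  if (!all(is.finite(resp))) stop("responses must be finite")
  X <- stats::model.matrix(fixed_form, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular fixed-effect design; aliased coefficient(s): ",
         paste(aliased, collapse = ", "))
  }
  bars <- lme4::findbars(formula)
  if (length(bars) < 1L) stop("formula must contain random-effect terms")
  gvars <- vapply(bars, function(b) deparse(b[[3L]]), character(1))
  for (g in gvars) data[[g]] <- factor(data[[g]])
  for (g in gvars) {
    if (nlevels(data[[g]]) < 2L) stop("grouping factor ", g,
                                      " needs >= 2 levels")
  }
  fit <- withCallingHandlers(
    lme4::lmer(formula, data = data, REML = FALSE, ...),
    message = function(m) {
      # a variance component on the zero boundary is a legitimate ML
      # optimum here, not a failure
      if (grepl("boundary \\(singular\\)", conditionMessage(m))) {
        invokeRestart("muffleMessage")
      }
    })
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
    stop("mixed-model fit did not converge: ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "),
         " (", fit@optinfo$feval, " function evaluations)")
  }
  co <- as.data.frame(summary(fit)$coefficients)
  fixed <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], t = co[, "t value"],
                      stringsAsFactors = FALSE)
  rownames(fixed) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual",
                                             "residual", vc$grp))
  ll <- stats::logLik(fit)
  structure(list(fixed = fixed, varcomp = varcomp,
                 loglik = as.numeric(ll), df = attr(ll, "df"),
                 nobs = stats::nobs(fit), formula = formula, model = fit),
            class = "evs_lmm")
}

#' @export
print.evs_lmm <- function(x, digits = 4, ...) {
  cat("Crossed random-intercepts model (ML)\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  logLik %.2f (df %d), n = %d\n", x$loglik, x$df, x$nobs))
  cat("Fixed effects:\n")
  print(format(x$fixed, digits = digits), row.names = FALSE)
  cat("Variance components:\n")
  vc <- data.frame(component = names(x$varcomp), variance = x$varcomp,
                   sd = sqrt(x$varcomp))
  print(format(vc, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.evs_lmm <- function(object, ...) {
  stats::setNames(object$fixed$estimate, object$fixed$term)
}

#' @export
logLik.evs_lmm <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
summary.evs_lmm <- function(object, ...) {
  object$fixed$significant <- abs(object$fixed$t) > 2
  object
}

#' Likelihood-ratio test of nested ML fits
#'
#' Compares two models fitted by maximum likelihood on the same data:
#' chi2 = 2 (logLik_full - logLik_reduced), with degrees of freedom equal
#' to the difference in parameter count and an upper-tail chi-squared
#' p-value (no boundary correction).  Tiny negative statistics from
#' optimizer noise are clipped to 0.  Accepts `evs_lmm` objects, `lm`
#' fits, or anything with a `logLik` method.
#'
#' @param full,reduced The nested pair (reduced must have fewer
#'   parameters and the same number of observations).
#' @return Object of class `evs_lrt`: list `chi2`, `df`, `p`.
#' @examples
#' x <- rnorm(20); y <- x + rnorm(20)
#' lrt(lm(y ~ x), lm(y ~ 1))
#' @export
lrt <- function(full, reduced) {
  ll_f <- stats::logLik(full)
  ll_r <- stats::logLik(reduced)
  n_f <- attr(ll_f, "nobs"); n_r <- attr(ll_r, "nobs")
  if (!is.null(n_f) && !is.null(n_r) && n_f != n_r) {
    stop("models were fitted on different numbers of observations")
  }
  df <- attr(ll_f, "df") - attr(ll_r, "df")
  if (df < 0) stop("'full' has fewer parameters than 'reduced'; not nested")
  chi2 <- 2 * (as.numeric(ll_f) - as.numeric(ll_r))
  if (chi2 < -1e-6) {
    stop("full model has lower likelihood than reduced; models not nested ",
         "or fit not converged (chi2 = ", format(chi2), ")")
  }
  chi2 <- max(chi2, 0)
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p), class = "evs_lrt")
}

#' @export
print.evs_lrt <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f, p = %.4g\n", x$df, x$chi2, x$p))
  invisible(x)
}

#' Likelihood-ratio ladder for familiarity and length effects
#'
#' Fits the intercept-only, familiarity-only, length-only, additive and
#' interaction models (all by ML, crossed subject and item intercepts) and
#' tests: familiarity against intercept-only (df 2), length against
#' intercept-only (df 1), and the familiarity x length interaction against
#' the additive model (df 2).
#'
#' @param data Data frame with the response, `familiarity`,
#'   `length_class`, `subject_id`, `item_id`.
#' @param response Name of the response column.
#' @return List of class `evs_lrt_ladder`: `tests` (data frame `effect`,
#'   `chi2`, `df`, `p`) and `fits` (the five `evs_lmm` objects:
#'   `intercept`, `familiarity`, `length`, `additive`, `interaction`).
#' @export
evs_lrt_ladder <- function(data, response = "offset_evs_ms") {
  f <- function(rhs) {
    stats::as.formula(paste(response, "~", rhs,
                            "+ (1 | subject_id) + (1 | item_id)"))
  }
  fits <- list(
    intercept = fit_evs_lmm(f("1"), data),
    familiarity = fit_evs_lmm(f("familiarity"), data),
    length = fit_evs_lmm(f("length_class"), data),
    additive = fit_evs_lmm(f("familiarity + length_class"), data),
    interaction = fit_evs_lmm(f("familiarity * length_class"), data))
  tests <- list(
    familiarity = lrt(fits$familiarity, fits$intercept),
    length = lrt(fits$length, fits$intercept),
    interaction = lrt(fits$interaction, fits$additive))
  tab <- data.frame(
    effect = names(tests),
    chi2 = vapply(tests, `[[`, numeric(1), "chi2"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(tests = tab, fits = fits), class = "evs_lrt_ladder")
}

#' @export
print.evs_lrt_ladder <- function(x, ...) {
  cat("Likelihood-ratio ladder\n")
  print(format(x$tests, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Coefficient significance by the |t| > 2 rule
#'
#' With large samples, absolute t-values above 2 indicate significance at
#' about the 5% level; the comparison is strict.
#'
#' @param fit An `evs_lmm` object (or anything with a `$fixed` table).
#' @param threshold Cutoff (default 2).
#' @return Named logical vector, one flag per coefficient.
#' @export
significance_by_t <- function(fit, threshold = 2) {
  stats::setNames(abs(fit$fixed$t) > threshold, fit$fixed$term)
}

#' Regress reading velocity on a subject-level EVS summary
#'
#' ML linear model of per-subject reading-velocity scores on the subject's
#' mean offset EVS (or mean GT/PT), compared against the intercept-only
#' model with a df-1 likelihood-ratio test.
#'
#' @param subject_summaries Data frame with one row per subject containing
#'   the predictor and velocity columns.
#' @param predictor Predictor column name (default `"mean_offset_evs"`).
#' @param velocity Velocity column name.
#' @return List of class `evs_velocity_fit`: `fit` (the `lm`), `slope`,
#'   `lrt` (`evs_lrt` vs intercept-only), `predictor`.
#' @export
velocity_regression <- function(subject_summaries,
                                predictor = "mean_offset_evs",
                                velocity = "velocity") {
  stopifnot(predictor %in% names(subject_summaries),
            velocity %in% names(subject_summaries))
  d <- subject_summaries[stats::complete.cases(
    subject_summaries[, c(predictor, velocity)]), , drop = FALSE]
  if (nrow(d) < 3L) stop("velocity regression needs >= 3 subjects")
  if (stats::sd(d[[predictor]]) == 0) stop("constant predictor")
  form <- stats::as.formula(paste(velocity, "~", predictor))
  fit <- stats::lm(form, data = d)
  null <- stats::lm(stats::as.formula(paste(velocity, "~ 1")), data = d)
  structure(list(fit = fit, slope = unname(stats::coef(fit)[2L]),
                 lrt = lrt(fit, null), predictor = predictor),
            class = "evs_velocity_fit")
}

#' @export
print.evs_velocity_fit <- function(x, ...) {
  cat(sprintf("Reading velocity ~ %s: slope %.4f; ", x$predictor, x$slope))
  print(x$lrt)
  invisible(x)
}
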