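# Trial estimands (per-arm means, covariate-adjusted treatment effect) and
# Rubin's rules for pooling across imputations.

#' Fit the covariate-adjusted analysis model
#'
#' Ordinary least squares of the follow-up score on its baseline value,
#' randomised treatment, age and sex; the treatment effect is the arm
#' coefficient with conventional model-based standard errors. Rows where
#' the outcome (or any covariate) is undefined are excluded, so applying
#' this to amputed data is exactly the complete-cases analysis.
#'
#' @param dat a (completed or amputed) cohort table.
#' @param outcome name of the follow-up score column (e.g. `"oks_fu"`).
#' @param baseline name of the baseline score column; defaults to the
#'   outcome with `_fu` replaced by `_base`.
#' @return a list: `effect`, `se`, `coefficients`, `n_used`.
#' @export
fit_analysis_model <- function(dat, outcome, baseline = NULL) {
  baseline <- baseline %||% sub("_fu$", "_base", outcome)
  d <- dat[, c(outcome, baseline, "arm", "age", "sex")]
  names(d)[1:2] <- c(".y", ".base")
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 6L) stopf("too few complete rows for the analysis model")
  fit <- stats::lm(.y ~ .base + arm + age + sex, data = d)
  sm <- summary(fit)$coefficients
  if (!"arm" %in% rownames(sm)) stopf("collinear design: arm dropped")
  list(effect = unname(sm["arm", 1]), se = unname(sm["arm", 2]),
       coefficients = stats::coef(fit), n_used = nrow(d))
}

#' Unadjusted mean outcomes
#'
#' Arithmetic mean and standard error of the mean of the follow-up score,
#' per arm and overall, over rows where the score is defined.
#'
#' @param dat a cohort table.
#' @param outcome follow-up score column name.
#' @return data frame with rows `arm0`, `arm1`, `overall` and columns
#'   `estimate`, `se`, `n_used`.
#' @export
unadjusted_means <- function(dat, outcome) {
  y <- dat[[outcome]]
  grp <- list(arm0 = y[dat$arm == 0 & !is.na(y)],
              arm1 = y[dat$arm == 1 & !is.na(y)],
              overall = y[!is.na(y)])
  if (!length(grp$arm0) || !length(grp$arm1)) stopf("empty arm")
  data.frame(
    estimand = names(grp),
    estimate = vapply(grp, mean, 0),
    se = vapply(grp, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0, 0),
    n_used = lengths(grp), row.names = NULL)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate = mean of the per-imputation estimates; within-imputation
#' variance `W` = mean squared standard error; between-imputation variance
#' `B` = sample variance of the estimates; total variance
#' `T = W + (1 + 1/m) B`. Degrees of freedom use the standard large-sample
#' formula `(m - 1)(1 + W / ((1 + 1/m) B))^2` (infinite when `B = 0`),
#' with the Barnard-Rubin small-sample adjustment available by flag.
#'
#' @param estimates numeric vector of per-imputation point estimates.
#' @param ses numeric vector of per-imputation standard errors.
#' @param barnard_rubin apply the small-sample df adjustment (requires
#'   `n_complete`).
#' @param n_complete complete-data residual degrees of freedom for the
#'   Barnard-Rubin adjustment.
#' @return an object of class `pooled_estimate`: `point`, `se`
#'   (`sqrt(T)`), `W`, `B`, `T`, `df`, `m`.
#' @export
rubin_pool <- function(estimates, ses, barnard_rubin = FALSE,
                       n_complete = NULL) {
  m <- length(estimates)
  if (m < 2L) stopf("Rubin's rules need m >= 2 imputations")
  if (length(ses) != m || anyNA(estimates) || anyNA(ses) ||
      any(!is.finite(estimates)) || any(!is.finite(ses)))
    stopf("estimates and ses must be finite vectors of equal length")
  point <- mean(estimates)
  W <- mean(ses^2)
  B <- stats::var(estimates)
  Tot <- W + (1 + 1 / m) * B
  df <- if (B == 0) Inf else (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
  if (barnard_rubin && is.finite(df)) {
    if (is.null(n_complete)) stopf("Barnard-Rubin adjustment needs n_complete")
    lam <- (1 + 1 / m) * B / Tot
    df_obs <- (n_complete + 1) / (n_complete + 3) * n_complete * (1 - lam)
    df <- 1 / (1 / df + 1 / df_obs)
  }
  structure(list(point = point, se = sqrt(Tot), W = W, B = B, T = Tot,
                 df = df, m = m), class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("<pooled_estimate> %.4f (se %.4f), m = %d, df = %.1f\n",
              x$point, x$se, x$m, x$df))
  cat(sprintf("  W = %.5f  B = %.5f  T = %.5f\n", x$W, x$B, x$T))
  invisible(x)
}

#' Confidence interval for a pooled estimate
#'
#' @param object a `pooled_estimate`.
#' @param parm ignored.
#' @param level confidence level.
#' @param ... ignored.
#' @return numeric length-2 interval using the t distribution on the
#'   pooled degrees of freedom.
#' @export
confint.pooled_estimate <- function(object, parm, level = 0.95, ...) {
  q <- if (is.finite(object$df)) stats::qt(1 - (1 - level) / 2, object$df)
  else stats::qnorm(1 - (1 - level) / 2)
  c(object$point - q * object$se, object$point + q * object$se)
}
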