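# Chained-equations multiple imputation with predictive mean matching and
# proportional-odds conditional models, and explicit convergence-failure
# accounting (failed chains are a first-class, countable outcome).

#' Specify one conditional imputation model
#'
#' @param target name of the variable to impute.
#' @param predictors character vector of predictor column names (must not
#'   contain the target).
#' @param method `"pmm"` (Bayesian linear regression + predictive mean
#'   matching) or `"ologit"` (proportional-odds draw).
#' @param k number of PMM donor candidates (>= 1).
#' @param levels for `"ologit"`: the full category-code set the stratum
#'   must exhibit (zero-cell scan); `NULL` disables the scan.
#' @return an object of class `imputation_model_spec`.
#' @export
imputation_model_spec <- function(target, predictors,
                                  method = c("pmm", "ologit"),
                                  k = 5L, levels = NULL) {
  method <- match.arg(method)
  if (target %in% predictors) stopf("target '%s' cannot predict itself", target)
  if (k < 1L) stopf("k must be >= 1")
  structure(list(target = target, predictors = predictors, method = method,
                 k = as.integer(k), levels = levels),
            class = "imputation_model_spec")
}

#' Specify a chained-equations imputation run
#'
#' @param level imputation level: `"score"`, `"subscale"`, or `"item"`.
#' @param models list of [imputation_model_spec()] covering every variable
#'   with missing entries at that level; visit order is the list order.
#' @param m number of imputations (>= 2).
#' @param cycles burn-in sweeps over the models per chain (a chain with a
#'   single incomplete variable needs only one sweep and is run that way).
#' @param by_arm impute separately within each treatment arm.
#' @param failure_tolerance abort the whole set when
#'   `failures > failure_tolerance * attempted` (default 0.5).
#' @param fallback_pooled if a by-arm set fails, retry once pooled with
#'   `arm` added as a predictor to every model.
#' @param item_numeric_mode items imputed by PMM as continuous variables
#'   (informational flag; the models' `method` fields govern behaviour).
#' @return an object of class `chained_spec`.
#' @export
chained_spec <- function(level = c("score", "subscale", "item"), models, m,
                         cycles = 10L, by_arm = FALSE,
                         failure_tolerance = 0.5, fallback_pooled = TRUE,
                         item_numeric_mode = FALSE) {
  level <- match.arg(level)
  if (m < 2L) stopf("m must be >= 2")
  if (failure_tolerance < 0 || failure_tolerance >= 1)
    stopf("failure_tolerance must be in [0, 1)")
  stopifnot(all(vapply(models, inherits, TRUE, "imputation_model_spec")))
  structure(list(level = level, models = models, m = as.integer(m),
                 cycles = as.integer(cycles), by_arm = by_arm,
                 failure_tolerance = failure_tolerance,
                 fallback_pooled = fallback_pooled,
                 item_numeric_mode = item_numeric_mode),
            class = "chained_spec")
}

#' Draw from the posterior of a normal linear regression
#'
#' One draw from the standard noninformative posterior: residual variance
#' from a scaled inverse chi-square, coefficients normal around the
#' least-squares fit. An intercept is added internally. Rank deficiency
#' signals non-convergence reason `"collinear"`; too few observed rows
#' signal `"overfit"`.
#'
#' @param y observed continuous response (no `NA`).
#' @param X predictor matrix (no intercept column).
#' @return list with `beta` (drawn coefficients, intercept first), `sigma`
#'   (drawn residual sd), `betahat` (posterior-mean coefficients).
#' @export
fit_bayes_linreg <- function(y, X) {
  X <- as.matrix(X)
  Xi <- cbind(`(Intercept)` = 1, X)
  n <- length(y); p <- ncol(Xi)
  if (n <= p + 2L)
    nonconvergence("overfit", sprintf("%d observed rows for %d parameters", n, p))
  XtX <- crossprod(Xi)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps) * max(diag(ch))))
    nonconvergence("collinear", "rank-deficient design matrix")
  betahat <- backsolve(ch, forwardsolve(t(ch), crossprod(Xi, y)))
  res <- y - drop(Xi %*% betahat)
  df <- n - p
  sigma2 <- sum(res^2) / stats::rchisq(1L, df)
  beta <- betahat + sqrt(sigma2) * backsolve(ch, stats::rnorm(p))
  list(beta = drop(beta), sigma = sqrt(sigma2), betahat = drop(betahat))
}

#' Impute continuous values by predictive mean matching
#'
#' Type-1 matching: predictions for missing rows come from one posterior
#' parameter draw, predictions for observed rows from the posterior-mean
#' fit; for each missing row one of the `k` observed rows with the nearest
#' prediction is drawn uniformly and its observed value assigned. Every
#' imputed value therefore belongs to the observed-value multiset.
#'
#' @param y response with `NA` at the rows to impute.
#' @param X full predictor matrix (no intercept column).
#' @param k donor-pool size; shrunk (with a warning) if fewer observed
#'   rows exist.
#' @param fit optional pre-computed [fit_bayes_linreg()] result on the
#'   observed rows.
#' @return `y` with missing entries filled by donor values.
#' @export
impute_pmm <- function(y, X, k = 5L, fit = NULL) {
  X <- as.matrix(X)
  mis <- which(is.na(y))
  if (!length(mis)) return(y)
  obs <- which(!is.na(y))
  if (k > length(obs)) {
    warning(sprintf("PMM donor pool shrunk from %d to %d", k, length(obs)))
    k <- length(obs)
  }
  if (is.null(fit)) fit <- fit_bayes_linreg(y[obs], X[obs, , drop = FALSE])
  yhat_obs <- fit$betahat[1] + drop(X[obs, , drop = FALSE] %*% fit$betahat[-1])
  yhat_mis <- fit$beta[1] + drop(X[mis, , drop = FALSE] %*% fit$beta[-1])
  so <- sort.int(yhat_obs, index.return = TRUE)
  s <- so$x; ys <- y[obs][so$ix]
  n_obs <- length(s)
  # the k nearest donors form a contiguous run in prediction-sorted order:
  # start from a window of width min(2k, n) around each target and shrink
  # it one element at a time from whichever end is farther, all targets at
  # once
  w <- min(2L * k, n_obs)
  lo <- findInterval(yhat_mis, s) - k + 1L
  lo <- pmin(pmax(lo, 1L), n_obs - w + 1L)
  hi <- lo + w - 1L
  while (w > k) {
    drop_hi <- abs(s[hi] - yhat_mis) >= abs(s[lo] - yhat_mis)
    hi <- hi - drop_hi
    lo <- lo + (1L - drop_hi)
    w <- w - 1L
  }
  pick <- lo + floor(stats::runif(length(mis)) * k)
  y[mis] <- ys[pick]
  y
}

#' Run one chained-equations imputation
#'
#' Missing entries are first filled by random draws from each variable's
#' observed values, then the conditional models are visited in order for
#' `cycles` sweeps, each refitting on the currently completed data and
#' re-imputing the originally missing entries; the final sweep's values are
#' returned. Any model failure in any sweep fails the whole chain with the
#' first failure's reason (a `promice_nonconvergence` condition).
#'
#' @param data a data frame with missing entries in the spec's target
#'   variables.
#' @param spec a [chained_spec()] (its `by_arm` flag is handled by
#'   [generate_imputations()]; `run_chain` imputes the data it is given).
#' @param seed integer seed.
#' @return the completed data frame.
#' @export
run_chain <- function(data, spec, seed) {
  set.seed(seed)
  miss <- lapply(spec$models, function(mdl) which(is.na(data[[mdl$target]])))
  names(miss) <- vapply(spec$models, `[[`, "", "target")
  active <- which(lengths(miss) > 0L)
  if (!length(active)) return(data)
  # initial fill: random draws from observed values
  for (i in active) {
    tg <- spec$models[[i]]$target
    obs <- data[[tg]][!is.na(data[[tg]])]
    if (!length(obs))
      nonconvergence("overfit", sprintf("'%s' has no observed values", tg))
    data[[tg]][miss[[i]]] <- sample(obs, length(miss[[i]]), replace = TRUE)
  }
  sweeps <- if (length(active) == 1L) 1L else spec$cycles
  # one numeric working matrix for the whole chain (column subsetting of a
  # matrix is much cheaper than repeated data-frame conversion)
  allcols <- unique(c(unlist(lapply(spec$models, `[[`, "predictors")),
                      names(miss)))
  M <- data.matrix(data[, allcols, drop = FALSE])
  warm <- vector("list", length(spec$models))   # previous sweep's MLEs
  for (sw in seq_len(sweeps)) {
    for (i in active) {
      mdl <- spec$models[[i]]
      tg <- mdl$target
      mi <- miss[[i]]
      X <- M[, mdl$predictors, drop = FALSE]
      yfit <- M[, tg]
      yfit[mi] <- NA                       # originally-missing are re-imputed
      if (mdl$method == "pmm") {
        M[, tg] <- impute_pmm(yfit, X, k = mdl$k)
      } else {
        obs_rows <- setdiff(seq_len(nrow(X)), mi)
        fit <- fit_ologit(yfit[obs_rows], X[obs_rows, , drop = FALSE],
                          all_levels = mdl$levels, start = warm[[i]])
        warm[[i]] <- list(beta = unname(fit$coefficients), zeta = fit$zeta)
        M[mi, tg] <- impute_ologit(fit, X[mi, , drop = FALSE])
      }
    }
  }
  for (tg in names(miss)) data[[tg]] <- M[, tg]
  data
}

run_chain_by_arm <- function(data, spec, seed) {
  if (!spec$by_arm) return(run_chain(data, spec, seed))
  out <- data
  for (a in sort(unique(data$arm))) {
    rows <- which(data$arm == a)
    out[rows, ] <- run_chain(data[rows, , drop = FALSE], spec,
                             derive_seed(seed, a + 1L))
  }
  out
}

#' Generate a multiply-imputed set
#'
#' Chains are attempted one at a time with fresh counter-derived sub-seeds
#' until `m` succeed; the whole set fails as soon as
#' `failures > failure_tolerance * attempted`. With `by_arm = TRUE` the
#' data are split by treatment arm and independent chains run per arm; if
#' the whole by-arm set fails and `fallback_pooled` is set, the set is
#' re-run once pooled with `arm` added as a predictor to every model.
#'
#' @param data the amputed data frame.
#' @param spec a [chained_spec()].
#' @param seed integer seed.
#' @return an object of class `promice_imps` (`completions`, `attempted`,
#'   `failures`, `reasons`, `fallback_used`), or of class
#'   `promice_failed_set` (`failed = TRUE`, `reason`, `failure_count`,
#'   `attempted`) when the set as a whole failed.
#' @export
generate_imputations <- function(data, spec, seed) {
  completions <- vector("list", spec$m)
  got <- 0L; attempted <- 0L; failures <- 0L; reasons <- character(0)
  while (got < spec$m) {
    attempted <- attempted + 1L
    res <- catch_nonconvergence(
      run_chain_by_arm(data, spec, derive_seed(seed, attempted)))
    if (is_failure(res)) {
      failures <- failures + 1L
      reasons <- c(reasons, res$reason)
      if (failures > spec$failure_tolerance * attempted) {
        if (spec$by_arm && spec$fallback_pooled) {
          pooled <- spec
          pooled$by_arm <- FALSE
          pooled$fallback_pooled <- FALSE
          pooled$models <- lapply(spec$models, function(mdl) {
            if (!"arm" %in% mdl$predictors)
              mdl$predictors <- c(mdl$predictors, "arm")
            mdl
          })
          out <- generate_imputations(data, pooled, derive_seed(seed, 0L))
          if (!is_failure(out)) {
            out$fallback_used <- TRUE
            # keep the by-arm failures in the convergence accounting
            out$attempted <- out$attempted + attempted
            out$failures <- out$failures + failures
            out$reasons <- c(reasons, out$reasons)
          } else {
            out$attempted <- out$attempted + attempted
            out$failure_count <- out$failure_count + failures
          }
          return(out)
        }
        return(structure(list(failed = TRUE, reason = reasons[1],
                              failure_count = failures,
                              attempted = attempted),
                         class = c("promice_failed_set", "list")))
      }
    } else {
      got <- got + 1L
      completions[[got]] <- res
    }
  }
  structure(list(completions = completions, m = spec$m,
                 attempted = attempted, failures = failures,
                 reasons = reasons, level = spec$level,
                 fallback_used = FALSE),
            class = "promice_imps")
}

#' @export
print.promice_imps <- function(x, ...) {
  cat(sprintf("<promice_imps> %d imputations (%s level), %d attempted, %d failed%s\n",
              x$m, x$level, x$attempted, x$failures,
              if (x$fallback_used) " [pooled fallback]" else ""))
  invisible(x)
}

#' @export
print.promice_failed_set <- function(x, ...) {
  cat(sprintf("<promice_failed_set> %d failures in %d attempts; first reason: %s\n",
              x$failure_count, x$attempted, x$reason))
  invisible(x)
}

#' Build the default chained-equations specification
#'
#' Encodes the framework's covariate and imputation-count conventions:
#' predictors are the baseline composite score(s), age, sex, height, ASA
#' grade and centre size (plus the treatment arm when imputation is pooled
#' across arms, and the baseline subscales at subscale/item level); within
#' a level every incomplete target additionally predicts, and is predicted
#' by, the other targets of that level (chained equations). The number of
#' imputations is 50 at score/subscale level; at item level it is 50 for
#' the full base-case sample, `round(100 * p)` for smaller samples, and 10
#' for exploratory scenarios. Imputation runs separately by arm except for
#' item-level models of instruments with more than five items (where
#' pooled imputation with arm as a covariate is the workable compromise).
#'
#' @param level `"score"`, `"subscale"`, or `"item"`.
#' @param sim an [instrument_sim()] or [instrument_spec()].
#' @param data the amputed cohort (used for observed category levels).
#' @param p proportion of missing data (for the item-level m rule).
#' @param base_case_n the full base-case sample size; when
#'   `nrow(data) == base_case_n` the item level uses m = 50.
#' @param exploratory use m = 10 at item level.
#' @param item_method `"ologit"` or `"pmm"` for item-level models.
#' @param m,cycles,by_arm,k overrides of the defaults.
#' @return a [chained_spec()].
#' @export
build_default_spec <- function(level = c("score", "subscale", "item"),
                               sim, data, p = NULL, base_case_n = NULL,
                               exploratory = FALSE,
                               item_method = c("ologit", "pmm"),
                               m = NULL, cycles = 10L, by_arm = NULL,
                               k = 5L) {
  level <- match.arg(level)
  item_method <- match.arg(item_method)
  spec <- if (inherits(sim, "instrument_sim")) sim$spec else sim
  comp_only <- composite_cols(spec)
  comp_only <- comp_only[!comp_only %in% paste0(spec$name, "_",
                                                names(spec$subscale_map))]
  base_comp <- paste0(comp_only, "_base")
  covs <- c(base_comp, "age", "sex", "height", "asa", "centre_size")
  has_subscales <- length(spec$subscale_map) > 0L
  if (level == "subscale" && !has_subscales)
    stopf("'%s' has no subscales", spec$name)
  if (level %in% c("subscale", "item") && has_subscales) {
    # the baseline subscales replace the baseline composite here: the
    # composite is their exact sum, so including both is collinear
    covs <- c(paste0(spec$name, "_", names(spec$subscale_map), "_base"),
              setdiff(covs, base_comp))
  }
  targets <- switch(level,
    score = paste0(composite_cols(spec)[
      !composite_cols(spec) %in% paste0(spec$name, "_",
                                        names(spec$subscale_map))], "_fu"),
    subscale = paste0(spec$name, "_", names(spec$subscale_map), "_fu"),
    item = item_cols(spec, "fu"))
  if (is.null(by_arm))
    by_arm <- !(level == "item" && spec$n_items > 5L)
  if (is.null(m)) {
    m <- if (level != "item") 50L
    else if (exploratory) 10L
    else if (!is.null(base_case_n) && nrow(data) == base_case_n) 50L
    else if (!is.null(p)) max(2L, as.integer(round(100 * p)))
    else 50L
  }
  covs <- covs[covs %in% names(data)]
  if (!by_arm) covs <- unique(c(covs, "arm"))
  models <- lapply(seq_along(targets), function(i) {
    tg <- targets[i]
    preds <- unique(c(setdiff(targets, tg), covs))
    if (level == "item" && item_method == "ologit") {
      lev <- sort(unique(data[[tg]][!is.na(data[[tg]])]))
      imputation_model_spec(tg, preds, "ologit", levels = lev)
    } else imputation_model_spec(tg, preds, "pmm", k = k)
  })
  chained_spec(level = level, models = models, m = m, cycles = cycles,
               by_arm = by_arm,
               item_numeric_mode = (level == "item" && item_method == "pmm"))
}
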