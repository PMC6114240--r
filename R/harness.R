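# Scenario orchestration: subsample -> truth -> ampute -> (CCA, MI x
# levels) -> estimate/pool, with valid-iteration accounting and
# performance summaries.

#' Define a simulation scenario
#'
#' A scenario fixes one instrument, one missingness configuration
#' (mechanism, proportion, pattern mixture), one sample size and a set of
#' analysis methods, and the iteration bookkeeping: the target number of
#' valid iterations and the attempt cap
#' (`attempt_cap_multiplier * n_valid_target`). An iteration is valid only
#' if every requested multiple-imputation method converged; invalid
#' iterations are replaced by further attempts up to the cap, and a
#' scenario that ends below target is flagged insufficient.
#'
#' @param sim an [instrument_sim()] (or [instrument_spec()]).
#' @param mixture a [pattern_mixture()] for the instrument.
#' @param p proportion of participants with missing data.
#' @param n sample size drawn (without replacement) from the base cohort
#'   each iteration.
#' @param methods subset of `c("cca", "mi_score", "mi_subscale",
#'   "mi_item_ologit", "mi_item_pmm")`.
#' @param outcome follow-up score column analysed; defaults to the
#'   instrument's first composite.
#' @param cohort_config a [cohort_config()] used to generate the base
#'   cohort when none is passed to [run_scenario()].
#' @param n_valid_target number of valid iterations wanted.
#' @param attempt_cap_multiplier cap = multiplier x target.
#' @param master_seed integer; all per-iteration seeds derive from it.
#' @param mechanism,predictor_weights passed to [amputation_config()].
#' @param exploratory,m,cycles,pmm_k imputation settings passed to
#'   [build_default_spec()]; `cycles` may be a named list giving a
#'   per-method burn-in (chained PMM models mix more slowly than
#'   proportional-odds ones and can need a longer burn-in).
#' @param base_case_n full base-case size for the item-level m rule.
#' @param redraw_subsample draw a fresh subsample every iteration (default)
#'   or fix one subsample for the whole scenario.
#' @return an object of class `promice_scenario`.
#' @export
scenario <- function(sim, mixture, p, n,
                     methods = c("cca", "mi_score"),
                     outcome = NULL, cohort_config = NULL,
                     n_valid_target = 1000L, attempt_cap_multiplier = 11L,
                     master_seed = 1L,
                     mechanism = "MAR",
                     predictor_weights = NULL,
                     exploratory = FALSE, m = NULL, cycles = 10L,
                     pmm_k = 5L, base_case_n = NULL,
                     redraw_subsample = TRUE) {
  if (inherits(sim, "instrument_spec")) sim <- instrument_sim(sim)
  known <- c("cca", "mi_score", "mi_subscale", "mi_item_ologit", "mi_item_pmm")
  if (!all(methods %in% known))
    stopf("unknown methods: %s", paste(setdiff(methods, known), collapse = ", "))
  outcome <- outcome %||% paste0(composite_cols(sim$spec)[1], "_fu")
  args <- list(instrument = sim$spec$name, p = p, mixture = mixture,
               mechanism = mechanism)
  if (!is.null(predictor_weights)) args$predictor_weights <- predictor_weights
  amp_config <- do.call(amputation_config, args)
  structure(list(sim = sim, amp_config = amp_config, p = p, n = as.integer(n),
                 methods = methods, outcome = outcome,
                 cohort_config = cohort_config,
                 n_valid_target = as.integer(n_valid_target),
                 attempt_cap = as.integer(attempt_cap_multiplier * n_valid_target),
                 master_seed = as.integer(master_seed),
                 exploratory = exploratory, m = m, cycles = cycles,
                 pmm_k = pmm_k, base_case_n = base_case_n,
                 redraw_subsample = redraw_subsample),
            class = "promice_scenario")
}

#' @export
print.promice_scenario <- function(x, ...) {
  cat(sprintf("<promice_scenario> %s: n=%d, p=%g (%s), methods: %s\n",
              x$sim$spec$name, x$n, x$p, x$amp_config$mechanism,
              paste(x$methods, collapse = ", ")))
  cat(sprintf("  target %d valid iterations (cap %d), master seed %d\n",
              x$n_valid_target, x$attempt_cap, x$master_seed))
  invisible(x)
}

mi_level <- function(method) switch(method,
  mi_score = "score", mi_subscale = "subscale",
  mi_item_ologit = "item", mi_item_pmm = "item")

#' Rebuild composite columns after imputation
#'
#' Item-level completions are re-scored from the imputed items;
#' subscale-level completions rebuild the composite as the sum of the
#' imputed subscales (equal-weight sum instruments); score-level
#' completions already imputed the composite directly.
#'
#' @param dat a completed cohort table.
#' @param sim the scenario's [instrument_sim()].
#' @param level the imputation level used.
#' @return the table with consistent follow-up score columns.
#' @export
complete_composites <- function(dat, sim, level) {
  spec <- sim$spec
  if (level == "item") return(rescore_cohort(dat, list(sim)))
  if (level == "subscale") {
    sub_cols <- paste0(spec$name, "_", names(spec$subscale_map), "_fu")
    dat[[paste0(spec$name, "_fu")]] <- rowSums(dat[, sub_cols, drop = FALSE])
  }
  dat
}

estimate_all <- function(dat, outcome) {
  mm <- unadjusted_means(dat, outcome)
  eff <- fit_analysis_model(dat, outcome)
  rbind(mm, data.frame(estimand = "treatment_effect",
                       estimate = eff$effect, se = eff$se,
                       n_used = eff$n_used))
}

#' Run one simulation iteration
#'
#' Pipeline: subsample the base cohort, extract the per-iteration truth
#' (complete-data estimates, captured before any data are deleted), ampute,
#' re-score under the partial-response rules, then estimate by
#' complete-cases analysis and/or the requested multiple-imputation
#' methods, pooling by Rubin's rules. The iteration is valid only if all
#' requested imputation methods converged.
#'
#' @param scn a [scenario()].
#' @param base_cohort the complete base cohort.
#' @param iteration_seed integer; all randomness in the iteration derives
#'   from it, so identical seeds give identical records.
#' @return list with `records` (long data frame of estimates), `valid`,
#'   `method_status` (per-MI-method convergence bookkeeping).
#' @export
run_iteration <- function(scn, base_cohort, iteration_seed) {
  sub <- if (scn$n < nrow(base_cohort))
    subsample(base_cohort, scn$n, derive_seed(iteration_seed, 1L))
  else base_cohort
  truth <- cbind(method = "truth", estimate_all(sub, scn$outcome),
                 m_used = NA_integer_)
  amp <- ampute(sub, scn$amp_config, derive_seed(iteration_seed, 2L))
  dat <- amp$data
  records <- truth
  method_status <- list()
  valid <- TRUE
  for (mth in scn$methods) {
    if (mth == "cca") {
      records <- rbind(records, cbind(method = "cca",
                                      estimate_all(dat, scn$outcome),
                                      m_used = NA_integer_))
      next
    }
    level <- mi_level(mth)
    item_method <- if (mth == "mi_item_pmm") "pmm" else "ologit"
    cyc <- if (is.list(scn$cycles)) scn$cycles[[mth]] %||% 10L else scn$cycles
    ispec <- build_default_spec(level, scn$sim, dat, p = scn$p,
                                base_case_n = scn$base_case_n,
                                exploratory = scn$exploratory,
                                item_method = item_method,
                                m = scn$m, cycles = cyc, k = scn$pmm_k)
    imps <- generate_imputations(dat, ispec,
                                 derive_seed(iteration_seed,
                                             10L + match(mth, scn$methods)))
    if (is_failure(imps)) {
      valid <- FALSE
      method_status[[mth]] <- list(ok = FALSE, reason = imps$reason,
                                   attempted = imps$attempted,
                                   failures = imps$failure_count)
      next
    }
    method_status[[mth]] <- list(ok = TRUE, attempted = imps$attempted,
                                 failures = imps$failures,
                                 fallback = imps$fallback_used)
    per_imp <- lapply(imps$completions, function(cc) {
      estimate_all(complete_composites(cc, scn$sim, level), scn$outcome)
    })
    est_names <- per_imp[[1]]$estimand
    pooled <- lapply(seq_along(est_names), function(j) {
      rubin_pool(vapply(per_imp, function(d) d$estimate[j], 0),
                 vapply(per_imp, function(d) d$se[j], 0))
    })
    records <- rbind(records, data.frame(
      method = mth, estimand = est_names,
      estimate = vapply(pooled, `[[`, 0, "point"),
      se = vapply(pooled, `[[`, 0, "se"),
      n_used = nrow(dat), m_used = imps$m))
  }
  list(records = records, valid = valid, method_status = method_status)
}

#' Run a full scenario
#'
#' Iterates with counter-derived sub-seeds until the valid-iteration target
#' is met or the attempt cap is reached; failed iterations are replaced,
#' never reused, and their convergence failures are counted. A scenario
#' ending below target is flagged `insufficient` (and should be excluded
#' from method comparisons).
#'
#' @param scn a [scenario()].
#' @param base_cohort optional pre-generated base cohort; otherwise
#'   generated once from `scn$cohort_config`.
#' @param verbose print one line per 50 attempts.
#' @return an object of class `prom_sim`: `records` (valid iterations
#'   only, with an `iteration` column), `valid_n`, `attempted`,
#'   `insufficient`, `chain_stats` (per method: chains attempted/failed,
#'   iteration-level failures).
#' @export
run_scenario <- function(scn, base_cohort = NULL, verbose = FALSE) {
  if (is.null(base_cohort)) {
    if (is.null(scn$cohort_config)) stopf("no base cohort and no cohort_config")
    base_cohort <- generate_cohort(scn$cohort_config,
                                   derive_seed(scn$master_seed, 0L))
  }
  if (!scn$redraw_subsample && scn$n < nrow(base_cohort))
    base_cohort <- subsample(base_cohort, scn$n,
                             derive_seed(scn$master_seed, 999983L))
  mi_methods <- setdiff(scn$methods, "cca")
  chain_stats <- stats::setNames(
    lapply(mi_methods, function(m) c(attempted = 0, failed = 0,
                                     iteration_failures = 0)),
    mi_methods)
  records <- vector("list", scn$n_valid_target)
  valid_n <- 0L; attempted <- 0L
  while (valid_n < scn$n_valid_target && attempted < scn$attempt_cap) {
    attempted <- attempted + 1L
    res <- run_iteration(scn, base_cohort,
                         derive_seed(scn$master_seed, attempted))
    for (mth in names(res$method_status)) {
      st <- res$method_status[[mth]]
      chain_stats[[mth]]["attempted"] <- chain_stats[[mth]]["attempted"] +
        st$attempted
      chain_stats[[mth]]["failed"] <- chain_stats[[mth]]["failed"] +
        st$failures
      if (!st$ok)
        chain_stats[[mth]]["iteration_failures"] <-
          chain_stats[[mth]]["iteration_failures"] + 1
    }
    if (res$valid) {
      valid_n <- valid_n + 1L
      records[[valid_n]] <- cbind(iteration = attempted, res$records)
    }
    if (verbose && attempted %% 50L == 0L)
      message(sprintf("  attempt %d: %d valid", attempted, valid_n))
  }
  structure(list(
    records = do.call(rbind, records[seq_len(valid_n)]),
    valid_n = valid_n, attempted = attempted,
    insufficient = valid_n < scn$n_valid_target,
    chain_stats = chain_stats, scenario = scn
  ), class = "prom_sim")
}

#' @export
print.prom_sim <- function(x, ...) {
  cat(sprintf("<prom_sim> %s n=%d p=%g: %d valid / %d attempted%s\n",
              x$scenario$sim$spec$name, x$scenario$n, x$scenario$p,
              x$valid_n, x$attempted,
              if (x$insufficient) " [INSUFFICIENT]" else ""))
  for (mth in names(x$chain_stats)) {
    cs <- x$chain_stats[[mth]]
    cat(sprintf("  %-16s chains %d/%d failed (%.1f%%), %d iteration failures\n",
                mth, cs["failed"], cs["attempted"],
                100 * cs["failed"] / max(cs["attempted"], 1),
                cs["iteration_failures"]))
  }
  invisible(x)
}

#' @export
summary.prom_sim <- function(object, ...) compute_performance(object)

#' Performance metrics of a scenario run
#'
#' For every method and estimand, errors are taken against the
#' same-iteration complete-data truth: `RMSE = sqrt(mean(err^2))`,
#' `MAE = mean(|err|)`, `bias = mean(err)`, plus the mean reported
#' standard error, the empirical sd of the estimates, and the
#' chain-convergence failure proportion (failed chains / attempted).
#'
#' @param x a `prom_sim` or a records data frame containing a `truth`
#'   method.
#' @param chain_stats optional chain bookkeeping (taken from the `prom_sim`
#'   when available).
#' @return a data frame of class `performance_summary`.
#' @export
compute_performance <- function(x, chain_stats = NULL) {
  records <- if (inherits(x, "prom_sim")) x$records else x
  chain_stats <- chain_stats %||%
    (if (inherits(x, "prom_sim")) x$chain_stats)
  if (is.null(records) || !nrow(records)) {
    return(structure(data.frame(), class = c("performance_summary",
                                             "data.frame")))
  }
  truth <- records[records$method == "truth",
                   c("iteration", "estimand", "estimate")]
  names(truth)[3] <- "truth"
  est <- records[records$method != "truth", ]
  if (!nrow(est)) {
    return(structure(data.frame(), class = c("performance_summary",
                                             "data.frame")))
  }
  mrg <- merge(est, truth, by = c("iteration", "estimand"), sort = FALSE)
  if (nrow(mrg) != nrow(est)) stopf("mismatched iteration sets")
  out <- do.call(rbind, lapply(split(mrg, list(mrg$method, mrg$estimand),
                                     drop = TRUE), function(d) {
    if (nrow(d) < 2L) stopf("need >= 2 valid iterations")
    err <- d$estimate - d$truth
    cfp <- if (!is.null(chain_stats) && d$method[1] %in% names(chain_stats)) {
      cs <- chain_stats[[d$method[1]]]
      unname(cs["failed"] / max(cs["attempted"], 1))
    } else NA_real_
    data.frame(method = d$method[1], estimand = d$estimand[1],
               n_iter = nrow(d),
               rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
               bias = mean(err), mean_se = mean(d$se),
               empirical_sd = stats::sd(d$estimate),
               convergence_failure_proportion = cfp)
  }))
  rownames(out) <- NULL
  structure(out, class = c("performance_summary", "data.frame"))
}

#' Combine scenario performance summaries into a report grid
#'
#' @param sims list of `prom_sim` objects (insufficient scenarios are kept
#'   but flagged).
#' @return a data frame (class `promice_report`) with one row per scenario
#'   x method x estimand, carrying `instrument`, `n`, `p`, `insufficient`
#'   and the performance columns; prints as a grid and plots RMSE against
#'   the missingness proportion, one panel per sample size.
#' @export
report <- function(sims) {
  rows <- lapply(sims, function(s) {
    perf <- compute_performance(s)
    if (!nrow(perf)) {
      return(data.frame(instrument = s$scenario$sim$spec$name,
                        n = s$scenario$n, p = s$scenario$p,
                        insufficient = s$insufficient,
                        method = NA_character_, estimand = NA_character_,
                        n_iter = 0L, rmse = NA_real_, mae = NA_real_,
                        bias = NA_real_, mean_se = NA_real_,
                        empirical_sd = NA_real_,
                        convergence_failure_proportion = NA_real_))
    }
    cbind(instrument = s$scenario$sim$spec$name, n = s$scenario$n,
          p = s$scenario$p, insufficient = s$insufficient, perf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("promice_report", "data.frame"))
}

#' @export
plot.promice_report <- function(x, estimand = "overall", ...) {
  d <- x[!is.na(x$method) & x$estimand == estimand & !x$insufficient, ]
  if (!nrow(d)) stopf("nothing to plot for estimand '%s'", estimand)
  sizes <- sort(unique(d$n))
  methods <- sort(unique(d$method))
  op <- graphics::par(mfrow = c(1, length(sizes)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nn in sizes) {
    dn <- d[d$n == nn, ]
    ps <- sort(unique(dn$p))
    ylim <- range(dn$rmse)
    graphics::plot(NA, xlim = range(ps), ylim = ylim, xlab = "proportion missing",
                   ylab = "RMSE", main = paste0("n = ", nn))
    for (i in seq_along(methods)) {
      dm <- dn[dn$method == methods[i], ]
      dm <- dm[order(dm$p), ]
      graphics::lines(dm$p, dm$rmse, col = i, type = "b", pch = i)
    }
    if (nn == sizes[1])
      graphics::legend("topleft", legend = methods, col = seq_along(methods),
                       pch = seq_along(methods), bty = "n", cex = 0.8)
  }
  invisible(x)
}
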