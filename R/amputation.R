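#' Define a missingness-pattern mixture
#'
#' A mixture of instrument-specific missingness patterns: each affected
#' participant is assigned one pattern, either unit nonresponse (all
#' follow-up items of the instrument deleted) or a specific item subset.
#'
#' @param instrument instrument name the patterns refer to.
#' @param patterns list; each element is the string `"unit"` or an integer
#'   vector of item indices to delete (non-empty).
#' @param probabilities numeric weights, one per pattern.
#' @param n_items number of items of the instrument (for index validation);
#'   optional.
#' @param normalize if `TRUE`, weights are renormalised to sum to 1 and the
#'   raw values kept in `$raw_probabilities`; if `FALSE`, they must already
#'   sum to 1 within 1e-12.
#' @return an object of class `pattern_mixture`.
#' @export
pattern_mixture <- function(instrument, patterns, probabilities,
                            n_items = NULL, normalize = FALSE) {
  if (length(patterns) != length(probabilities))
    stopf("patterns and probabilities must have equal length")
  if (!length(patterns)) stopf("empty pattern mixture")
  if (any(probabilities < 0)) stopf("probabilities must be >= 0")
  patterns <- lapply(patterns, function(p) {
    if (identical(p, "unit")) return("unit")
    p <- as.integer(p)
    if (!length(p)) stopf("a pattern must delete at least one item")
    if (!is.null(n_items) && any(p < 1L | p > n_items))
      stopf("pattern item index out of range for %d items", n_items)
    sort(p)
  })
  raw <- probabilities
  if (normalize) probabilities <- probabilities / sum(probabilities)
  else if (abs(sum(probabilities) - 1) > 1e-12)
    stopf("probabilities must sum to 1 (got %.6f); use normalize = TRUE",
          sum(probabilities))
  structure(list(instrument = instrument, patterns = patterns,
                 probabilities = probabilities, raw_probabilities = raw),
            class = "pattern_mixture")
}

#' @export
print.pattern_mixture <- function(x, ...) {
  lab <- vapply(x$patterns, function(p)
    if (identical(p, "unit")) "unit" else paste0("item ", paste(p, collapse = ",")),
    "")
  cat(sprintf("<pattern_mixture> %s: %d patterns\n", x$instrument, length(lab)))
  for (i in seq_along(lab))
    cat(sprintf("  %-18s %6.2f%%\n", lab[i], 100 * x$probabilities[i]))
  invisible(x)
}

#' Configure an amputation mechanism
#'
#' Describes how missingness is imposed on complete follow-up data for one
#' instrument: the target proportion `p` of affected participants, the
#' missing-at-random predictor weights, and the mixture of nonresponse
#' patterns assigned to affected participants.
#'
#' Under `"MAR"` the per-participant propensity is
#' `plogis(alpha + score)` where `score` is the standardised weighted sum
#' of standardised predictors (treatment arm, age, baseline composite,
#' height, ASA grade, centre size; categorical predictors enter by integer
#' coding) and `alpha` is calibrated so the mean propensity equals `p`.
#' Under `"MCAR"` every propensity equals `p`.
#'
#' @param instrument instrument name.
#' @param p target proportion of participants with missing data, in (0,1).
#' @param mixture a [pattern_mixture()] for the instrument.
#' @param mechanism `"MAR"` or `"MCAR"`.
#' @param predictor_weights named weights for
#'   `(arm, age, baseline, height, asa, centre)`; ignored under MCAR.
#'   The defaults make older participants with worse baseline scores more
#'   likely to be missing.
#' @return an object of class `amputation_config`.
#' @export
amputation_config <- function(instrument, p, mixture,
                              mechanism = c("MAR", "MCAR"),
                              predictor_weights = c(arm = 0.3, age = 0.5,
                                                    baseline = -0.5,
                                                    height = 0.2, asa = 0.3,
                                                    centre = 0.2)) {
  mechanism <- match.arg(mechanism)
  if (p <= 0 || p >= 1) stopf("p must be in (0,1)")
  if (!inherits(mixture, "pattern_mixture")) stopf("mixture must be a pattern_mixture")
  if (!identical(mixture$instrument, instrument))
    stopf("mixture is for instrument '%s'", mixture$instrument)
  structure(list(instrument = instrument, p = p, mixture = mixture,
                 mechanism = mechanism,
                 predictor_weights = predictor_weights),
            class = "amputation_config")
}

baseline_score_cols <- function(dat, instrument) {
  # baseline composite column(s) of an instrument as present in the table
  cand <- paste0(instrument, "_base")
  if (cand %in% names(dat)) return(cand)
  hits <- grep(paste0("^", instrument, "_[a-z]+_base$"), names(dat), value = TRUE)
  # exclude item columns and prefer top-level components (pcs/mcs)
  hits <- hits[!grepl("_i[0-9]+$", hits)]
  if (!length(hits)) stopf("no baseline composite column for '%s'", instrument)
  hits
}

#' Missingness propensity under an amputation configuration
#'
#' @param cohort a complete cohort table.
#' @param config an [amputation_config()].
#' @return numeric vector of per-participant probabilities of being flagged
#'   missing; under MAR their mean equals `config$p` to within 1e-6.
#' @export
missingness_propensity <- function(cohort, config) {
  if (config$mechanism == "MCAR") return(rep(config$p, nrow(cohort)))
  w <- config$predictor_weights
  base_cols <- baseline_score_cols(cohort, config$instrument)
  pred <- cbind(arm = cohort$arm, age = cohort$age,
                height = cohort$height, asa = cohort$asa,
                centre = cohort$centre_size)
  if (any(!is.finite(as.matrix(pred))) ||
      any(!is.finite(as.matrix(cohort[, base_cols]))))
    stopf("non-finite predictor values")
  score <- rep(0, nrow(cohort))
  for (nm in c("arm", "age", "height", "asa", "centre"))
    score <- score + w[[nm]] * scale_unit(pred[, nm])
  for (bc in base_cols)                       # weight split across components
    score <- score + (w[["baseline"]] / length(base_cols)) *
      scale_unit(cohort[[bc]])
  score <- scale_unit(score)
  if (all(score == 0)) return(rep(config$p, nrow(cohort)))   # MCAR limit
  alpha <- calibrate_intercept(score, config$p)
  stats::plogis(alpha + score)
}

calibrate_intercept <- function(score, p, tol = 1e-6) {
  f <- function(a) mean(stats::plogis(a + score)) - p
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) stopf("intercept calibration not bracketed")
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) < tol) return(mid)
    if (v > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Impose missingness on complete follow-up data
#'
#' Each participant is independently flagged missing with their propensity;
#' each flagged participant receives one pattern drawn from the mixture and
#' exactly those follow-up items are deleted. Baseline data are never
#' touched. Derived follow-up score columns are re-computed under the
#' instrument's partial-response scoring rules (so, e.g., a composite
#' tolerating two missing items survives small item patterns).
#'
#' @param cohort a cohort table, complete at follow-up for the instrument.
#' @param config an [amputation_config()].
#' @param seed integer seed.
#' @return a list of class `promice_amputation`: `data` (the amputed
#'   cohort), `indicator` (logical, flagged missing), `pattern` (index into
#'   the mixture, `NA` for unaffected), `propensity`.
#' @export
ampute <- function(cohort, config, seed) {
  fu_cols <- grep(paste0("^", config$instrument, "_fu_i[0-9]+$"),
                  names(cohort), value = TRUE)
  if (!length(fu_cols)) stopf("cohort has no follow-up items for '%s'",
                              config$instrument)
  if (anyNA(cohort[, fu_cols]))
    stopf("cohort must be complete at follow-up before amputation")
  prop <- missingness_propensity(cohort, config)
  set.seed(seed)
  flagged <- stats::runif(nrow(cohort)) < prop
  pat <- rep(NA_integer_, nrow(cohort))
  n_items <- length(fu_cols)
  if (any(flagged)) {
    pat[flagged] <- sample.int(length(config$mixture$patterns), sum(flagged),
                               replace = TRUE,
                               prob = config$mixture$probabilities)
    for (k in seq_along(config$mixture$patterns)) {
      rows <- which(pat == k)
      if (!length(rows)) next
      pk <- config$mixture$patterns[[k]]
      idx <- if (identical(pk, "unit")) seq_len(n_items) else pk
      cohort[rows, fu_cols[idx]] <- NA
    }
  }
  cohort <- rescore_cohort(cohort)
  structure(list(data = cohort, indicator = flagged, pattern = pat,
                 propensity = prop, config = config),
            class = "promice_amputation")
}

#' @export
print.promice_amputation <- function(x, ...) {
  cat(sprintf("<promice_amputation> %s: %d/%d participants affected (target p = %g, %s)\n",
              x$config$instrument, sum(x$indicator), length(x$indicator),
              x$config$p, x$config$mechanism))
  invisible(x)
}
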