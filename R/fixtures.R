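# Ready-made configurations binding the modules together: the three
# standard instruments, a default utility value set, the observed
# missingness-pattern mixtures, and the base-case cohort configurations.

#' Standard instrument fixtures
#'
#' `oks_spec()`: a knee-outcome instrument of 12 five-level items scored
#' 0-4 each (composite 0-48, higher = better), tolerating up to two
#' missing items by mean substitution, with a configurable default
#' partition into pain (items 1-7) and function (items 8-12) subscales
#' each tolerating one missing item. The subscale partition is a shipped
#' fixture, not a validated mapping.
#'
#' `sf12_spec()`: a 12-item generic health survey with mixed item levels,
#' scored into norm-based physical (`pcs`) and mental (`mcs`) components
#' by a configurable two-factor weight matrix standardised against a
#' reference sample (mean 50, sd 10); all items are required.
#'
#' `eq5d_spec()`: a five-dimension, three-level utility instrument scored
#' by an additive value set; any missing dimension leaves the utility
#' undefined.
#'
#' @return an [instrument_spec()].
#' @export
oks_spec <- function() {
  instrument_spec(
    name = "oks", item_levels = rep(5L, 12L), code_base = 0L,
    composite_rule = "sum", max_missing_allowed = 2L,
    subscale_map = list(pain = 1:7, fn = 8:12),
    subscale_max_missing = c(pain = 1L, fn = 1L))
}

#' @rdname oks_spec
#' @export
sf12_spec <- function() {
  levels <- c(5L, 3L, 3L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L)
  w <- matrix(0, 12, 2, dimnames = list(NULL, c("pcs", "mcs")))
  w[1:6, "pcs"] <- 1; w[7:12, "mcs"] <- 1
  w[7, "pcs"] <- 0.25; w[3, "mcs"] <- 0.25   # mild cross-loading
  instrument_spec(
    name = "sf12", item_levels = levels, code_base = 1L,
    composite_rule = "weighted-normed", max_missing_allowed = 0L,
    norm_model = norm_scoring_model(w))
}

#' @rdname oks_spec
#' @export
eq5d_spec <- function(tariff = default_tariff()) {
  instrument_spec(
    name = "eq5d", item_levels = rep(3L, 5L), code_base = 1L,
    composite_rule = "tariff", max_missing_allowed = 0L, tariff = tariff)
}

#' Default utility value set
#'
#' An additive three-level tariff of the standard UK form: constant
#' decrement 0.081 for any departure from full health, per-dimension
#' level-2/level-3 decrements, and an extra 0.269 if any dimension is at
#' the worst level. Full health (11111) is anchored at 1 exactly.
#'
#' @return an [eq5d_value_set()].
#' @export
default_tariff <- function() {
  dec <- rbind(mobility = c(0.069, 0.314),
               self_care = c(0.104, 0.214),
               usual_activities = c(0.036, 0.094),
               pain_discomfort = c(0.123, 0.386),
               anxiety_depression = c(0.071, 0.236))
  eq5d_value_set(constant = 0.081, decrements = dec,
                 worst_level_extra = 0.269)
}

mixture_path <- function(file) {
  system.file("extdata", "mixtures", file, package = "promice",
              mustWork = TRUE)
}

read_mixture <- function(file, instrument, n_items) {
  d <- utils::read.csv(mixture_path(file), stringsAsFactors = FALSE)
  patterns <- lapply(d$items, function(s) {
    if (s == "unit") "unit"
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  pattern_mixture(instrument, patterns, d$raw_percent,
                  n_items = n_items, normalize = TRUE)
}

#' Load a named fixture
#'
#' The registry binds together instrument specifications, the observed
#' missingness-pattern mixtures (stored as CSV under `extdata/mixtures`,
#' renormalised to a simplex with the raw percentages retained), and the
#' base-case cohort configurations (n = 1030 knee-score-like, 1160
#' utility-like, 797 health-survey-like).
#'
#' @param name fixture name; an unknown name raises an error listing the
#'   registry.
#' @return the fixture object (validated at construction).
#' @export
load_fixture <- function(name) {
  registry <- list(
    oks = function() oks_spec(),
    sf12 = function() sf12_spec(),
    eq5d = function() eq5d_spec(),
    default_tariff = function() default_tariff(),
    oks_observed_mixture = function()
      read_mixture("oks_observed.csv", "oks", 12L),
    oks_unit_mixture = function()
      pattern_mixture("oks", list("unit"), 1, n_items = 12L),
    oks_70pct_item_mixture = function() oks_70pct_item_mixture(),
    sf12_observed_mixture = function()
      read_mixture("sf12_observed.csv", "sf12", 12L),
    eq5d_observed_mixture = function()
      read_mixture("eq5d_observed.csv", "eq5d", 5L),
    oks_base_case = function()
      cohort_config(1030L, list(instrument_sim(oks_spec()))),
    eq5d_base_case = function()
      cohort_config(1160L, list(instrument_sim(eq5d_spec(),
                                               orientation = -1))),
    sf12_base_case = function()
      cohort_config(797L, list(instrument_sim(sf12_spec())))
  )
  if (!name %in% names(registry))
    stopf("unknown fixture '%s'; available: %s", name,
          paste(names(registry), collapse = ", "))
  registry[[name]]()
}

oks_70pct_item_mixture <- function() {
  # observed item patterns reweighted to 70% total mass, unit pattern 30%
  obs <- load_fixture("oks_observed_mixture")
  is_unit <- vapply(obs$patterns, identical, TRUE, "unit")
  item_p <- obs$probabilities[!is_unit]
  pattern_mixture("oks",
                  c(list("unit"), obs$patterns[!is_unit]),
                  c(0.3, 0.7 * item_p / sum(item_p)),
                  n_items = 12L)
}
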