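#' Define a multi-item instrument
#'
#' An instrument specification describes the structure of a multi-item
#' patient-reported outcome measure (PROM): how many items it has, how many
#' ordered categories each item takes, how category codes map to numeric
#' item scores, how the composite is formed, and how many missing items the
#' scoring manual tolerates (missing items being substituted by the mean of
#' the observed item scores).
#'
#' @param name identifier, used as the prefix of item columns
#'   (`"<name>_<timepoint>_i<k>"`).
#' @param item_levels integer vector, number of ordered categories per item.
#' @param item_codes list of integer vectors, the admissible category codes
#'   per item (defaults to `code_base + 0:(L-1)`).
#' @param item_score_values list of numeric vectors, the score attached to
#'   each category of each item (defaults to `0:(L-1)`, the modern
#'   sum-score convention).
#' @param composite_rule one of `"sum"` (equal-weight sum with
#'   mean-substitution), `"weighted-normed"` (norm-based two-factor scores,
#'   see [score_normed()]), `"tariff"` (utility value set, see
#'   [score_eq5d()]).
#' @param max_missing_allowed maximum number of missing items for which the
#'   composite may still be computed (mean-substitution rule).
#' @param subscale_map named list of item-index vectors defining subscales;
#'   may be empty.
#' @param subscale_max_missing named integer vector (same names as
#'   `subscale_map`): per-subscale missing-item tolerance. Defaults to 0.
#' @param code_base first category code (0 for 0-based instruments such as
#'   the knee score, 1 for 1-based ones).
#' @param tariff an [eq5d_value_set()] (required for `"tariff"`).
#' @param norm_model a [norm_scoring_model()] (required for
#'   `"weighted-normed"`).
#' @return an object of class `instrument_spec`.
#' @export
instrument_spec <- function(name, item_levels,
                            item_codes = NULL, item_score_values = NULL,
                            composite_rule = c("sum", "weighted-normed", "tariff"),
                            max_missing_allowed = 0L,
                            subscale_map = list(),
                            subscale_max_missing = NULL,
                            code_base = 0L,
                            tariff = NULL, norm_model = NULL) {
  composite_rule <- match.arg(composite_rule)
  n_items <- length(item_levels)
  if (n_items < 1L) stopf("instrument needs at least one item")
  if (is.null(item_codes))
    item_codes <- lapply(item_levels, function(L) code_base + 0:(L - 1L))
  if (is.null(item_score_values))
    item_score_values <- lapply(item_levels, function(L) as.numeric(0:(L - 1L)))
  if (length(item_codes) != n_items || length(item_score_values) != n_items)
    stopf("item_codes / item_score_values must have one entry per item")
  for (i in seq_len(n_items)) {
    if (length(item_codes[[i]]) != item_levels[i] ||
        length(item_score_values[[i]]) != item_levels[i])
      stopf("item %d: codes/scores inconsistent with %d levels", i, item_levels[i])
  }
  if (max_missing_allowed >= n_items)
    stopf("max_missing_allowed must be < n_items")
  if (length(subscale_map)) {
    idx <- unlist(subscale_map)
    if (any(idx < 1L | idx > n_items)) stopf("subscale_map indices out of range")
    if (is.null(subscale_max_missing))
      subscale_max_missing <- stats::setNames(rep(0L, length(subscale_map)),
                                              names(subscale_map))
  }
  if (composite_rule == "tariff" && is.null(tariff))
    stopf("composite_rule 'tariff' requires a value set")
  # attainable score range under the sum rule
  score_range <- if (composite_rule == "sum") {
    c(sum(vapply(item_score_values, min, 0)),
      sum(vapply(item_score_values, max, 0)))
  } else if (composite_rule == "tariff") {
    unname(c(score_eq5d_state(rep(3L, 5L), tariff), 1))
  } else c(NA_real_, NA_real_)
  structure(list(
    name = name, n_items = n_items, item_levels = as.integer(item_levels),
    item_codes = item_codes, item_score_values = item_score_values,
    composite_rule = composite_rule,
    max_missing_allowed = as.integer(max_missing_allowed),
    subscale_map = subscale_map, subscale_max_missing = subscale_max_missing,
    score_range = score_range, code_base = as.integer(code_base),
    tariff = tariff, norm_model = norm_model
  ), class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("<instrument_spec> %s: %d items, rule=%s, max missing=%d\n",
              x$name, x$n_items, x$composite_rule, x$max_missing_allowed))
  if (!all(is.na(x$score_range)))
    cat(sprintf("  composite range [%g, %g]\n", x$score_range[1], x$score_range[2]))
  if (length(x$subscale_map))
    cat("  subscales:", paste(names(x$subscale_map), collapse = ", "), "\n")
  invisible(x)
}

# ---- response validation -----------------------------------------------

as_resp_matrix <- function(spec, resp) {
  if (is.null(dim(resp))) resp <- matrix(resp, nrow = 1L)
  if (ncol(resp) != spec$n_items)
    stopf("response has %d items, instrument '%s' has %d",
          ncol(resp), spec$name, spec$n_items)
  mode(resp) <- "numeric"
  for (i in seq_len(ncol(resp))) {
    v <- resp[, i]
    bad <- !is.na(v) & !(v %in% spec$item_codes[[i]])
    if (any(bad))
      stopf("item %d of '%s': code %s not admissible", i, spec$name,
            paste(unique(v[bad]), collapse = ","))
  }
  resp
}

item_scores_matrix <- function(spec, resp) {
  # map category codes to numeric item scores, preserving NA
  out <- resp
  for (i in seq_len(ncol(resp))) {
    m <- match(resp[, i], spec$item_codes[[i]])
    out[, i] <- spec$item_score_values[[i]][m]
  }
  out
}

# ---- composite and subscale scoring ------------------------------------

sum_score <- function(scores, idx, max_missing) {
  s <- scores[, idx, drop = FALSE]
  k <- length(idx)
  nmiss <- rowSums(is.na(s))
  mean_obs <- rowMeans(s, na.rm = TRUE)
  val <- k * mean_obs             # mean-substitution == k * mean(observed)
  val[nmiss > max_missing] <- NA_real_
  val[nmiss == k] <- NA_real_
  val
}

#' Score an instrument composite
#'
#' Applies the instrument's composite rule with its partial-response
#' tolerance: up to `max_missing_allowed` missing items are substituted by
#' the arithmetic mean of the observed item scores; more missing items make
#' the composite undefined (`NA`). The mean-substituted value is kept
#' fractional (no rounding).
#'
#' @param spec an [instrument_spec()].
#' @param resp an item-response vector (length `n_items`) or a matrix with
#'   one row per respondent; entries are category codes, `NA` = missing.
#' @return numeric vector of composite scores (`NA` where undefined). For
#'   `"weighted-normed"` instruments use [score_normed()]; for `"tariff"`
#'   instruments this delegates to [score_eq5d()].
#' @export
score_composite <- function(spec, resp) {
  resp <- as_resp_matrix(spec, resp)
  switch(spec$composite_rule,
    sum = sum_score(item_scores_matrix(spec, resp),
                    seq_len(spec$n_items), spec$max_missing_allowed),
    tariff = score_eq5d(resp, spec$tariff),
    `weighted-normed` =
      stopf("instrument '%s' produces norm-based scores; use score_normed()",
            spec$name)
  )
}

#' Score instrument subscales
#'
#' Each subscale is scored independently with its own missing-item
#' tolerance, so a subscale can be defined while the composite is not (and
#' vice versa).
#'
#' @inheritParams score_composite
#' @return a matrix (respondents x subscales) of subscale scores.
#' @export
score_subscales <- function(spec, resp) {
  if (!length(spec$subscale_map)) stopf("'%s' defines no subscales", spec$name)
  resp <- as_resp_matrix(spec, resp)
  scores <- item_scores_matrix(spec, resp)
  out <- vapply(names(spec$subscale_map), function(nm) {
    sum_score(scores, spec$subscale_map[[nm]], spec$subscale_max_missing[[nm]])
  }, numeric(nrow(resp)))
  if (nrow(resp) == 1L) out <- matrix(out, nrow = 1L,
                                      dimnames = list(NULL, names(spec$subscale_map)))
  out
}

# ---- EQ-5D tariff ------------------------------------------------------

#' Define a 3-level utility value set
#'
#' Additive tariff for a five-dimension, three-level descriptive system:
#' full health (state 11111) is anchored at utility 1; any departure incurs
#' a constant decrement; each dimension at level 2 or 3 incurs its own
#' decrement; and if any dimension is at the worst level an extra decrement
#' applies once.
#'
#' @param constant decrement applied once for any state other than 11111.
#' @param decrements 5 x 2 matrix; `decrements[d, l-1]` is the decrement for
#'   dimension `d` at level `l` (l = 2, 3). Rows: mobility, self-care,
#'   usual activities, pain/discomfort, anxiety/depression.
#' @param worst_level_extra decrement applied once if any dimension is at
#'   level 3.
#' @return an object of class `eq5d_value_set`.
#' @export
eq5d_value_set <- function(constant, decrements, worst_level_extra) {
  decrements <- as.matrix(decrements)
  if (!all(dim(decrements) == c(5L, 2L))) stopf("decrements must be 5 x 2")
  if (constant < 0 || worst_level_extra < 0 || any(decrements < 0))
    stopf("all decrements must be >= 0")
  vs <- structure(list(full_health_anchor = 1, constant = constant,
                       decrements = decrements,
                       worst_level_extra = worst_level_extra),
                  class = "eq5d_value_set")
  stopifnot(score_eq5d_state(rep(1L, 5L), vs) == 1)   # anchor identity
  vs
}

score_eq5d_state <- function(state, vs) {
  dec <- 0
  for (d in 1:5) if (state[d] > 1L) dec <- dec + vs$decrements[d, state[d] - 1L]
  not_full <- any(state != 1L)
  vs$full_health_anchor - vs$constant * not_full - dec -
    vs$worst_level_extra * any(state == 3L)
}

#' Score EQ-5D-3L health states
#'
#' Utility of each five-dimension, three-level health state under an
#' additive value set. There is no partial-response rule: any missing
#' dimension makes the utility undefined.
#'
#' @param resp vector of 5 level codes (1-3) or a matrix with one row per
#'   respondent.
#' @param tariff an [eq5d_value_set()].
#' @return numeric utilities (`NA` where any dimension is missing).
#' @export
score_eq5d <- function(resp, tariff) {
  if (is.null(dim(resp))) resp <- matrix(resp, nrow = 1L)
  if (ncol(resp) != 5L) stopf("EQ-5D-3L responses have 5 dimensions")
  mode(resp) <- "numeric"
  bad <- !is.na(resp) & !(resp %in% 1:3)
  if (any(bad)) stopf("EQ-5D-3L levels must be in 1..3")
  dec <- matrix(0, nrow(resp), ncol(resp))
  for (d in 1:5) for (l in 2:3)
    dec[resp[, d] == l & !is.na(resp[, d]), d] <- tariff$decrements[d, l - 1L]
  any_na <- rowSums(is.na(resp)) > 0L
  not_full <- rowSums(resp != 1L) > 0L
  any3 <- rowSums(resp == 3L) > 0L
  u <- tariff$full_health_anchor - tariff$constant * not_full -
    rowSums(dec) - tariff$worst_level_extra * any3
  u[any_na] <- NA_real_
  u
}

# ---- norm-based two-factor scoring -------------------------------------

#' Define a norm-based two-factor scoring model
#'
#' A configurable stand-in for proprietary physical/mental component
#' scoring of 12-item generic health surveys: each component is a weighted
#' sum of all item scores, standardised against a stored reference sample
#' so that the reference population scores mean 50, standard deviation 10
#' on each component. The model must be calibrated with
#' [calibrate_norm_model()] before scoring.
#'
#' @param weights `n_items x 2` numeric matrix of item weights; column
#'   names name the components (default `pcs`, `mcs`).
#' @return an object of class `norm_scoring_model` (uncalibrated).
#' @export
norm_scoring_model <- function(weights) {
  weights <- as.matrix(weights)
  if (is.null(colnames(weights))) colnames(weights) <- c("pcs", "mcs")
  structure(list(weights = weights, reference_mean = NULL,
                 reference_sd = NULL), class = "norm_scoring_model")
}

#' Calibrate a norm-based scoring model against a reference sample
#'
#' Stores the mean and standard deviation of each component's weighted sum
#' over a complete reference item matrix, so that [score_normed()] maps the
#' reference population to mean 50, sd 10.
#'
#' @param model a [norm_scoring_model()].
#' @param ref_items complete respondent x item matrix of category codes.
#' @return the calibrated model.
#' @export
calibrate_norm_model <- function(model, ref_items) {
  ref_items <- as.matrix(ref_items)
  if (anyNA(ref_items)) stopf("reference sample must be complete")
  ws <- ref_items %*% model$weights
  model$reference_mean <- colMeans(ws)
  model$reference_sd <- apply(ws, 2, stats::sd)
  if (any(model$reference_sd <= 0)) stopf("degenerate reference sample")
  model
}

#' Score norm-based components
#'
#' All items are required: any missing item makes both components
#' undefined. Component score = `50 + 10 * (weighted sum - reference mean)
#' / reference sd`.
#'
#' @param model a calibrated [norm_scoring_model()].
#' @param resp item-response vector or matrix of category codes.
#' @return matrix (respondents x components) of scores, `NA` rows where any
#'   item is missing.
#' @export
score_normed <- function(model, resp) {
  if (is.null(model$reference_mean))
    stopf("norm scoring model is not calibrated")
  if (is.null(dim(resp))) resp <- matrix(resp, nrow = 1L)
  mode(resp) <- "numeric"
  if (ncol(resp) != nrow(model$weights))
    stopf("response has %d items, model expects %d", ncol(resp),
          nrow(model$weights))
  any_na <- rowSums(is.na(resp)) > 0L
  resp0 <- resp; resp0[is.na(resp0)] <- 0
  ws <- resp0 %*% model$weights
  out <- sweep(sweep(ws, 2, model$reference_mean), 2, model$reference_sd, "/")
  out <- 50 + 10 * out
  out[any_na, ] <- NA_real_
  out
}

# ---- missingness pattern classification --------------------------------

#' Classify the missingness pattern of item responses
#'
#' Partitions respondents into `complete` (no missing item),
#' `unit_nonresponse` (all items missing) and `item_nonresponse` (some but
#' not all missing). The partition is exhaustive and mutually exclusive.
#'
#' @param resp item-response vector or matrix (`NA` = missing).
#' @return for a single vector, a list with `type` and (for
#'   item-nonresponse) `items`, the missing item indices; for a matrix, a
#'   character vector of types with missing indices available via
#'   [classify_pattern_labels()].
#' @export
classify_pattern <- function(resp) {
  if (is.null(dim(resp))) {
    nmiss <- sum(is.na(resp))
    if (nmiss == 0L) return(list(type = "complete"))
    if (nmiss == length(resp)) return(list(type = "unit_nonresponse"))
    return(list(type = "item_nonresponse", items = which(is.na(resp))))
  }
  nmiss <- rowSums(is.na(resp))
  type <- rep("item_nonresponse", nrow(resp))
  type[nmiss == 0L] <- "complete"
  type[nmiss == ncol(resp)] <- "unit_nonresponse"
  type
}

#' Label missingness patterns of a response matrix
#'
#' One label per respondent: `"complete"`, `"unit"`, or `"item:i,j,..."`
#' listing the missing item indices. Used to tabulate realised pattern
#' frequencies against a configured pattern mixture.
#'
#' @param resp respondent x item matrix.
#' @return character vector of pattern labels.
#' @export
classify_pattern_labels <- function(resp) {
  nmiss <- rowSums(is.na(resp))
  lab <- rep("complete", nrow(resp))
  lab[nmiss == ncol(resp)] <- "unit"
  part <- which(nmiss > 0L & nmiss < ncol(resp))
  if (length(part)) {
    lab[part] <- vapply(part, function(r)
      paste0("item:", paste(which(is.na(resp[r, ])), collapse = ",")), "")
  }
  lab
}

# ---- item column naming ------------------------------------------------

#' Item column names for a cohort table
#'
#' Itemised responses live in columns `"<instrument>_<timepoint>_i<k>"`.
#'
#' @param spec an [instrument_spec()] or its name.
#' @param timepoint `"base"` or `"fu"`.
#' @param n_items required when `spec` is given by name.
#' @return character vector of column names.
#' @export
item_cols <- function(spec, timepoint = c("base", "fu"), n_items = NULL) {
  timepoint <- match.arg(timepoint)
  if (inherits(spec, "instrument_spec")) {
    n_items <- spec$n_items; name <- spec$name
  } else name <- spec
  paste0(name, "_", timepoint, "_i", seq_len(n_items))
}
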