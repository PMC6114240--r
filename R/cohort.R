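#' Per-instrument simulation settings
#'
#' Binds an [instrument_spec()] to the parameters of the latent-trait
#' item-generation model: each participant has a latent health score per
#' timepoint; item `i` is generated by thresholding
#' `a * orientation * theta + e_i` (e standard normal) at cutpoints chosen
#' so the marginal category frequencies match `probs_*`. The shared latent
#' induces coherent inter-item and item-composite correlation
#' (graded-response style).
#'
#' @param spec an [instrument_spec()].
#' @param probs_base,probs_fu lists (one numeric simplex per item) of
#'   marginal category probabilities at baseline / follow-up. Defaults
#'   depend on the number of levels and emulate an elderly surgical trial
#'   population: worse health at baseline, improved at follow-up, with a
#'   rare worst category at follow-up.
#' @param discrimination loading `a` of items on the latent (default 1.3).
#' @param orientation `+1` if higher category codes mean better health,
#'   `-1` if worse (utility-style instruments).
#' @return an object of class `instrument_sim`.
#' @export
instrument_sim <- function(spec, probs_base = NULL, probs_fu = NULL,
                           discrimination = 1.3, orientation = 1) {
  if (is.null(probs_base))
    probs_base <- lapply(spec$item_levels, default_item_probs,
                         timepoint = "base", orientation = orientation)
  if (is.null(probs_fu))
    probs_fu <- lapply(spec$item_levels, default_item_probs,
                       timepoint = "fu", orientation = orientation)
  for (pl in list(probs_base, probs_fu)) {
    if (length(pl) != spec$n_items) stopf("need one probability vector per item")
    for (i in seq_len(spec$n_items)) {
      p <- pl[[i]]
      if (length(p) != spec$item_levels[i]) stopf("item %d: wrong prob length", i)
      if (any(p <= 0) || abs(sum(p) - 1) > 1e-8)
        stopf("item %d: category probabilities must be a positive simplex (no empty category in expectation)", i)
    }
  }
  structure(list(spec = spec, probs_base = probs_base, probs_fu = probs_fu,
                 a = discrimination, orientation = orientation),
            class = "instrument_sim")
}

default_item_probs <- function(L, timepoint, orientation) {
  # category marginals, indexed by ascending code
  if (orientation < 0) {                      # higher code = worse health
    if (L == 3L) return(switch(timepoint, base = c(0.35, 0.50, 0.15),
                               fu = c(0.55, 0.38, 0.07)))
    stopf("no default marginals for %d-level reversed items", L)
  }
  if (L == 5L) return(switch(timepoint,
                             base = c(0.15, 0.30, 0.30, 0.18, 0.07),
                             fu   = c(0.04, 0.10, 0.20, 0.33, 0.33)))
  if (L == 3L) return(switch(timepoint, base = c(0.25, 0.45, 0.30),
                             fu = c(0.15, 0.40, 0.45)))
  if (L == 2L) return(switch(timepoint, base = c(0.45, 0.55),
                             fu = c(0.30, 0.70)))
  stopf("no default marginals for %d-level items", L)
}

#' Configure a synthetic two-arm trial cohort
#'
#' Defines the generative model for a complete randomised-trial dataset:
#' covariates (age, sex, height, ASA physical-status grade, recruiting
#' centre size), a baseline latent health score loading on standardised
#' covariates, a follow-up latent that autoregresses on baseline with an
#' additive treatment effect, and itemised instrument responses produced by
#' latent thresholding (see [instrument_sim()]).
#'
#' Latent scales are constructed to have unit variance, so `tau` is the
#' treatment effect in latent standard-deviation units;
#' [implied_composite_effect()] maps it to the composite scale.
#'
#' @param n number of participants.
#' @param instruments list of [instrument_sim()] (or [instrument_spec()],
#'   wrapped with defaults).
#' @param allocation proportion allocated to arm 1 (permuted-block exact).
#' @param tau treatment effect on the follow-up latent (default 0: the
#'   near-null effect typical of the emulated trial setting).
#' @param rho autoregression of the follow-up latent on baseline; the
#'   default lands the baseline-follow-up composite correlation in the
#'   low-to-moderate band.
#' @param loadings_base,loadings_fu named loadings of the latents on the
#'   standardised covariates `(age, sex, height, asa, centre)`; squared
#'   norms (plus `rho^2` at follow-up) must stay below 1.
#' @param covariates list overriding covariate distribution parameters:
#'   `age_mean, age_sd, p_female, height_mean_male, height_mean_female,
#'   height_sd, asa_probs, centre_probs`.
#' @param target_correlation_band numeric length-2; the generated cohort's
#'   baseline-follow-up composite correlation is checked against this band
#'   (warning at n >= 500 if outside).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n, instruments,
                          allocation = 0.5, tau = 0, rho = 0.55,
                          loadings_base = c(age = -0.35, sex = -0.05,
                                            height = 0.05, asa = -0.25,
                                            centre = 0),
                          loadings_fu = c(age = -0.10, sex = 0, height = 0,
                                          asa = -0.10, centre = 0),
                          covariates = list(),
                          target_correlation_band = c(0.3, 0.6)) {
  if (allocation <= 0 || allocation >= 1) stopf("allocation must be in (0,1)")
  if (target_correlation_band[1] <= 0 || target_correlation_band[2] >= 1 ||
      diff(target_correlation_band) <= 0)
    stopf("target_correlation_band must be an increasing interval in (0,1)")
  instruments <- lapply(instruments, function(x) {
    if (inherits(x, "instrument_spec")) instrument_sim(x) else x
  })
  names(instruments) <- vapply(instruments, function(x) x$spec$name, "")
  if (sum(loadings_base^2) >= 1) stopf("baseline loadings too large (variance > 1)")
  if (rho^2 + sum(loadings_fu^2) >= 1) stopf("rho and follow-up loadings too large")
  cov_def <- list(age_mean = 70, age_sd = 8, p_female = 0.57,
                  height_mean_male = 175, height_mean_female = 162,
                  height_sd = 7, asa_probs = c(0.25, 0.60, 0.15),
                  centre_probs = c(0.2, 0.5, 0.3))
  cov_def[names(covariates)] <- covariates
  structure(list(n = as.integer(n), instruments = instruments,
                 allocation = allocation, tau = tau, rho = rho,
                 loadings_base = loadings_base, loadings_fu = loadings_fu,
                 covariates = cov_def,
                 target_correlation_band = target_correlation_band),
            class = "cohort_config")
}

item_thresholds <- function(probs, a) {
  # cutpoints on the scale of a*theta + e (sd sqrt(a^2+1)) reproducing the
  # marginal category probabilities when theta ~ N(0, 1)
  s <- sqrt(a^2 + 1)
  stats::qnorm(cumsum(probs)[-length(probs)]) * s
}

gen_items <- function(theta, sim, timepoint) {
  probs <- if (timepoint == "base") sim$probs_base else sim$probs_fu
  spec <- sim$spec
  n <- length(theta)
  out <- matrix(NA_integer_, n, spec$n_items)
  lat_mean <- sim$a * sim$orientation * theta
  for (i in seq_len(spec$n_items)) {
    thr <- item_thresholds(probs[[i]], sim$a)
    y <- lat_mean + stats::rnorm(n)
    out[, i] <- spec$item_codes[[i]][findInterval(y, thr) + 1L]
  }
  colnames(out) <- item_cols(spec, timepoint)
  out
}

#' Generate a complete synthetic trial cohort
#'
#' Draws covariates, arm allocation, baseline and follow-up latent health
#' scores, itemised instrument responses, and all derived composite and
#' subscale columns. The generated table is complete (no missing cells) and
#' its stored composites equal a re-scoring of its items.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; generation is reproducible given the seed.
#' @return a `data.frame` (class `promice_cohort`) with columns `id`,
#'   `arm`, `age`, `sex`, `height`, `asa`, `centre_size`, the item columns
#'   `"<instrument>_<timepoint>_i<k>"`, and derived score columns. The
#'   achieved baseline-follow-up composite correlations are stored in
#'   `attr(, "achieved_correlation")`; the (possibly calibrated) instrument
#'   simulation settings in `attr(, "instrument_sims")`.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n
  cv <- config$covariates
  n1 <- round(n * config$allocation)
  arm <- sample(c(rep(0L, n - n1), rep(1L, n1)))
  age <- pmin(pmax(stats::rnorm(n, cv$age_mean, cv$age_sd), 40), 95)
  sex <- stats::rbinom(n, 1L, cv$p_female)          # 1 = female
  height <- stats::rnorm(n, ifelse(sex == 1L, cv$height_mean_female,
                                   cv$height_mean_male), cv$height_sd)
  asa <- sample.int(3L, n, replace = TRUE, prob = cv$asa_probs)
  centre <- sample.int(3L, n, replace = TRUE, prob = cv$centre_probs)

  z <- cbind(age = scale_unit(age), sex = scale_unit(sex),
             height = scale_unit(height), asa = scale_unit(asa),
             centre = scale_unit(centre))
  wb <- config$loadings_base; wf <- config$loadings_fu
  theta_b <- drop(z %*% wb) + sqrt(1 - sum(wb^2)) * stats::rnorm(n)
  resid_sd <- sqrt(1 - config$rho^2 - sum(wf^2))
  theta_f <- config$rho * theta_b + drop(z %*% wf) +
    config$tau * arm + resid_sd * stats::rnorm(n)

  dat <- data.frame(id = seq_len(n), arm = arm, age = age, sex = sex,
                    height = height, asa = asa, centre_size = centre)
  sims <- config$instruments
  for (nm in names(sims)) {
    dat <- cbind(dat, gen_items(theta_b, sims[[nm]], "base"),
                 gen_items(theta_f, sims[[nm]], "fu"))
    # calibrate a norm-based model on this cohort's baseline items
    sp <- sims[[nm]]$spec
    if (sp$composite_rule == "weighted-normed" &&
        is.null(sp$norm_model$reference_mean)) {
      ref <- as.matrix(dat[, item_cols(sp, "base")])
      sims[[nm]]$spec$norm_model <- calibrate_norm_model(sp$norm_model, ref)
    }
  }
  dat <- rescore_cohort(dat, sims)
  attr(dat, "instrument_sims") <- sims
  achieved <- vapply(names(sims), function(nm) {
    cols <- composite_cols(sims[[nm]]$spec)
    stats::cor(dat[[paste0(cols[1], "_base")]], dat[[paste0(cols[1], "_fu")]])
  }, 0)
  attr(dat, "achieved_correlation") <- achieved
  band <- config$target_correlation_band
  if (n >= 500 && any(achieved < band[1] | achieved > band[2]))
    warning(sprintf("baseline-follow-up composite correlation outside [%g, %g]: %s",
                    band[1], band[2],
                    paste(sprintf("%s=%.2f", names(achieved), achieved),
                          collapse = ", ")))
  class(dat) <- c("promice_cohort", "data.frame")
  dat
}

scale_unit <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Names of the composite/score columns of an instrument
#'
#' Sum-rule instruments have one composite (named after the instrument)
#' plus any subscales; norm-based instruments have one column per
#' component; tariff instruments one utility column.
#' @param spec an [instrument_spec()].
#' @return character vector of score-column stems (append `"_base"` /
#'   `"_fu"` for the timepoint).
#' @export
composite_cols <- function(spec) {
  switch(spec$composite_rule,
    sum = c(spec$name, if (length(spec$subscale_map))
      paste0(spec$name, "_", names(spec$subscale_map))),
    `weighted-normed` = paste0(spec$name, "_", colnames(spec$norm_model$weights)),
    tariff = spec$name)
}

#' Recompute derived score columns from item columns
#'
#' Applies instrument scoring (composite, subscales, norm-based components,
#' utilities) to the item columns at both timepoints, overwriting or
#' creating the derived columns. Scores that the partial-response rules
#' leave undefined become `NA`.
#'
#' @param dat a cohort table.
#' @param sims list of [instrument_sim()] (or specs); defaults to
#'   `attr(dat, "instrument_sims")`.
#' @return the table with refreshed score columns.
#' @export
rescore_cohort <- function(dat, sims = NULL) {
  sims <- sims %||% attr(dat, "instrument_sims")
  if (is.null(sims)) stopf("no instrument settings attached to the cohort")
  for (sim in sims) {
    spec <- if (inherits(sim, "instrument_sim")) sim$spec else sim
    for (tp in c("base", "fu")) {
      cols <- item_cols(spec, tp)
      if (!all(cols %in% names(dat))) next
      items <- as.matrix(dat[, cols])
      if (spec$composite_rule == "weighted-normed") {
        sc <- score_normed(spec$norm_model, items)
        for (j in colnames(sc))
          dat[[paste0(spec$name, "_", j, "_", tp)]] <- sc[, j]
      } else {
        dat[[paste0(spec$name, "_", tp)]] <- score_composite(spec, items)
        if (length(spec$subscale_map)) {
          sc <- score_subscales(spec, items)
          for (j in colnames(sc))
            dat[[paste0(spec$name, "_", j, "_", tp)]] <- sc[, j]
        }
      }
    }
  }
  dat
}

#' Subsample a cohort without replacement
#'
#' @param cohort a cohort table.
#' @param n number of participants to keep (`n <=` cohort size).
#' @param seed integer seed.
#' @return a cohort of `n` distinct participants (attributes preserved).
#' @export
subsample <- function(cohort, n, seed) {
  if (n > nrow(cohort)) stopf("cannot subsample %d from %d rows", n, nrow(cohort))
  set.seed(seed)
  keep <- sort(sample.int(nrow(cohort), n))
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("instrument_sims", "achieved_correlation"))
    attr(out, a) <- attr(cohort, a)
  out
}

#' Treatment effect implied on the composite scale
#'
#' Maps the latent-scale treatment effect `tau` of a [cohort_config()] to
#' the follow-up composite scale of one instrument by integrating the
#' thresholding model over the latent distribution:
#' `E[composite | arm = 1] - E[composite | arm = 0]`, each expectation
#' computed by Gauss-quadrature over `theta ~ N(tau * arm, 1)`. Serves as
#' the generative truth for treatment-effect recovery checks. Supported for
#' sum-rule and tariff instruments.
#'
#' @param config a [cohort_config()].
#' @param instrument instrument name.
#' @return numeric scalar, composite-scale effect of arm 1 vs arm 0.
#' @export
implied_composite_effect <- function(config, instrument) {
  sim <- config$instruments[[instrument]]
  if (is.null(sim)) stopf("unknown instrument '%s'", instrument)
  spec <- sim$spec
  grid <- seq(-6, 6, length.out = 241)
  wts <- stats::dnorm(grid); wts <- wts / sum(wts)
  e_comp <- function(mu) {
    th <- grid + mu
    # P(code = l | theta) per item: categorical given a*o*theta + e
    if (spec$composite_rule == "sum") {
      tot <- 0
      for (i in seq_len(spec$n_items)) {
        thr <- item_thresholds(sim$probs_fu[[i]], sim$a)
        cum <- vapply(thr, function(t)
          stats::pnorm(t - sim$a * sim$orientation * th), numeric(length(th)))
        p <- cbind(cum, 1)
        p <- p - cbind(0, cum)
        tot <- tot + sum(wts * (p %*% spec$item_score_values[[i]]))
      }
      tot
    } else if (spec$composite_rule == "tariff") {
      vs <- spec$tariff
      p_lev <- lapply(seq_len(spec$n_items), function(i) {
        thr <- item_thresholds(sim$probs_fu[[i]], sim$a)
        cum <- vapply(thr, function(t)
          stats::pnorm(t - sim$a * sim$orientation * th), numeric(length(th)))
        p <- cbind(cum, 1); p - cbind(0, cum)
      })
      dec <- 0
      for (d in 1:5) for (l in 2:3)
        dec <- dec + vs$decrements[d, l - 1] * p_lev[[d]][, l]
      p_all1 <- Reduce(`*`, lapply(p_lev, function(p) p[, 1]))
      p_no3 <- Reduce(`*`, lapply(p_lev, function(p) 1 - p[, 3]))
      u <- vs$full_health_anchor - vs$constant * (1 - p_all1) - dec -
        vs$worst_level_extra * (1 - p_no3)
      sum(wts * u)
    } else stopf("implied effect unsupported for rule '%s'", spec$composite_rule)
  }
  e_comp(config$tau) - e_comp(0)
}

#' @export
print.promice_cohort <- function(x, ...) {
  cat(sprintf("<promice_cohort> %d participants, %d columns\n", nrow(x), ncol(x)))
  ac <- attr(x, "achieved_correlation")
  if (!is.null(ac))
    cat("  baseline-follow-up composite correlation:",
        paste(sprintf("%s=%.2f", names(ac), ac), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a cohort table as CSV
#'
#' Missing cells are encoded as empty fields.
#' @param dat cohort table.
#' @param path file path.
#' @export
write_cohort_csv <- function(dat, path) {
  utils::write.csv(dat, path, row.names = FALSE, na = "")
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, na.strings = "")
}
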