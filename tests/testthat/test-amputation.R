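test_that("pattern mixtures validate their simplex and indices", {
  expect_error(pattern_mixture("oks", list("unit", 3), c(0.5, 0.4)),
               "sum to 1")
  m <- pattern_mixture("oks", list("unit", 3), c(73.1, 26.9),
                       normalize = TRUE)
  expect_equal(sum(m$probabilities), 1)
  expect_equal(m$raw_probabilities, c(73.1, 26.9))
  expect_error(pattern_mixture("oks", list(13L), 1, n_items = 12),
               "out of range")
  expect_error(pattern_mixture("oks", list(integer(0)), 1), "at least one")
})

test_that("MCAR and zero-weight MAR give constant propensity p", {
  ch <- oks_cohort(400)
  cfgm <- amputation_config("oks", 0.2, load_fixture("oks_observed_mixture"),
                            mechanism = "MCAR")
  expect_equal(missingness_propensity(ch, cfgm), rep(0.2, 400))
  cfg0 <- amputation_config("oks", 0.2, load_fixture("oks_observed_mixture"),
                            predictor_weights = c(arm = 0, age = 0,
                                                  baseline = 0, height = 0,
                                                  asa = 0, centre = 0))
  expect_equal(missingness_propensity(ch, cfg0), rep(0.2, 400))
})

test_that("MAR intercept calibration hits the target mean propensity", {
  ch <- oks_cohort(5000, seed = 19)
  for (p in c(0.05, 0.10, 0.20, 0.40)) {
    cfg <- amputation_config("oks", p, load_fixture("oks_observed_mixture"))
    expect_lt(abs(mean(missingness_propensity(ch, cfg)) - p), 1.1e-6)
  }
})

test_that("propensity is monotone in the weighted score", {
  ch <- oks_cohort(2000, seed = 20)
  mk <- function(w_age) amputation_config(
    "oks", 0.2, load_fixture("oks_observed_mixture"),
    predictor_weights = c(arm = 0.3, age = w_age, baseline = -0.5,
                          height = 0.2, asa = 0.3, centre = 0.2))
  r1 <- cor(ch$age, missingness_propensity(ch, mk(0.5)), method = "spearman")
  r2 <- cor(ch$age, missingness_propensity(ch, mk(1.0)), method = "spearman")
  expect_gt(r1, 0)
  expect_gte(r2, r1)
})

test_that("amputation deletes exactly the drawn patterns, follow-up only", {
  ch <- oks_cohort(2000, seed = 21)
  amp <- amputed_oks(cohort = ch, p = 0.2, seed = 22)
  dat <- amp$data
  fu <- as.matrix(dat[, item_cols(oks_spec(), "fu")])
  base <- as.matrix(dat[, item_cols(oks_spec(), "base")])
  expect_false(anyNA(base))                       # baseline never deleted
  expect_false(anyNA(fu[!amp$indicator, ]))       # unaffected rows untouched
  expect_identical(dat$age, ch$age)
  # each affected row misses exactly its assigned pattern's items
  mix <- amp$config$mixture
  for (r in which(amp$indicator)[1:50]) {
    pk <- mix$patterns[[amp$pattern[r]]]
    want <- if (identical(pk, "unit")) 1:12 else pk
    expect_identical(unname(which(is.na(fu[r, ]))), as.integer(want))
  }
})

test_that("unit-only mixture yields unit nonresponse for every affected row", {
  ch <- oks_cohort(800, seed = 23)
  amp <- amputed_oks(cohort = ch, mixture = load_fixture("oks_unit_mixture"),
                     seed = 24)
  fu <- as.matrix(amp$data[, item_cols(oks_spec(), "fu")])
  lab <- classify_pattern_labels(fu)
  expect_true(all(lab[amp$indicator] == "unit"))
  expect_true(all(lab[!amp$indicator] == "complete"))
})

test_that("realised proportion and pattern frequencies match the mixture", {
  ch <- oks_cohort(20000, seed = 25)
  amp <- amputed_oks(cohort = ch, p = 0.2, seed = 26)
  n <- nrow(ch)
  expect_lt(abs(mean(amp$indicator) - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  mix <- amp$config$mixture
  counts <- tabulate(amp$pattern[amp$indicator], length(mix$patterns))
  gof <- chisq.test(counts, p = mix$probabilities)
  expect_gt(gof$p.value, 0.001)
})

test_that("missingness regresses on the score under MAR but not MCAR", {
  ch <- oks_cohort(4000, seed = 27)
  amp_mar <- amputed_oks(cohort = ch, p = 0.2, seed = 28)
  amp_mcar <- amputed_oks(cohort = ch, p = 0.2, seed = 29,
                          mechanism = "MCAR")
  score <- qlogis(amp_mar$propensity)       # linear in the weighted score
  f_mar <- glm(amp_mar$indicator ~ score, family = binomial)
  z_mar <- summary(f_mar)$coefficients["score", "z value"]
  expect_gt(z_mar, 3)
  f_mcar <- glm(amp_mcar$indicator ~ score, family = binomial)
  z_mcar <- summary(f_mcar)$coefficients["score", "z value"]
  expect_lt(abs(z_mcar), 4)
})

test_that("amputation is deterministic given the seed", {
  ch <- oks_cohort(500, seed = 30)
  a1 <- amputed_oks(cohort = ch, seed = 31)
  a2 <- amputed_oks(cohort = ch, seed = 31)
  expect_identical(a1$data, a2$data)
  expect_identical(a1$pattern, a2$pattern)
})

test_that("partial-response scoring survives small item patterns", {
  ch <- oks_cohort(2000, seed = 32)
  amp <- amputed_oks(cohort = ch, p = 0.3, seed = 33)
  fu <- as.matrix(amp$data[, item_cols(oks_spec(), "fu")])
  nmiss <- rowSums(is.na(fu))
  # rows with <= 2 missing items keep a composite; > 2 lose it
  expect_false(anyNA(amp$data$oks_fu[nmiss <= 2]))
  expect_true(all(is.na(amp$data$oks_fu[nmiss > 2])))
})
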