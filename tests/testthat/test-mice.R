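test_that("the regression posterior draw centres on the truth", {
  set.seed(51)
  n <- 5000
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(2, 1, -1, 0.5)                      # intercept first
  y <- beta[1] + drop(X %*% beta[-1]) + rnorm(n, sd = 2)
  fit <- fit_bayes_linreg(y, X)
  ref <- lm(y ~ X)
  se <- sqrt(diag(vcov(ref)))
  expect_true(all(abs(fit$beta - beta) < 4 * se))
  expect_equal(fit$betahat, unname(coef(ref)), tolerance = 1e-8)
  # noiseless linear data: the draw collapses onto the exact coefficients
  y0 <- beta[1] + drop(X %*% beta[-1])
  fit0 <- fit_bayes_linreg(y0, X)
  expect_equal(fit0$beta, beta, tolerance = 1e-6)
})

test_that("degenerate designs fail with structured reasons", {
  set.seed(52)
  X <- matrix(rnorm(60), 30)
  Xdup <- cbind(X, X[, 1])
  y <- rnorm(30)
  expect_nonconvergence(fit_bayes_linreg(y, Xdup), "collinear")
  expect_nonconvergence(fit_bayes_linreg(y[1:5], X[1:5, ]), "overfit")
})

test_that("PMM imputes only observed values (support preservation)", {
  set.seed(53)
  for (i in 1:200) {
    n <- sample(40:80, 1)
    X <- matrix(rnorm(n * 2), n)
    y <- drop(X %*% c(1, -1)) + rnorm(n)
    y[sample(n, ceiling(n / 4))] <- NA
    out <- impute_pmm(y, X, k = 5)
    expect_false(anyNA(out))
    expect_true(all(out[is.na(y)] %in% y[!is.na(y)]))
  }
})

test_that("PMM with k = 1 returns the matching donor on noiseless data", {
  set.seed(54)
  X <- matrix(seq(-2, 2, length.out = 41))
  y <- drop(3 + 2 * X)
  X2 <- rbind(X, 0)                   # missing row duplicates the x = 0 row
  y2 <- c(y, NA)
  out <- impute_pmm(y2, X2, k = 1)
  expect_equal(out[42], 3, tolerance = 1e-6)    # the x = 0 donor's y
  # fully observed input is a no-op
  expect_identical(impute_pmm(y, X, k = 3), y)
})

test_that("PMM shrinks an oversized donor pool with a warning", {
  set.seed(55)
  y <- c(rnorm(8), NA, NA)
  X <- matrix(rnorm(20), 10)
  expect_warning(out <- impute_pmm(y, X, k = 10), "shrunk")
  expect_true(all(out[9:10] %in% y[1:8]))
})

test_that("imputed composites stay inside the observed score support", {
  amp <- amputed_oks(n = 300, seed = 56)
  dat <- amp$data
  spec <- build_default_spec("score", instrument_sim(oks_spec()), dat, m = 3)
  imps <- generate_imputations(dat, spec, 57)
  obs <- dat$oks_fu[!is.na(dat$oks_fu)]
  for (cc in imps$completions) {
    filled <- cc$oks_fu[is.na(dat$oks_fu)]
    expect_true(all(filled %in% obs))
    expect_true(all(filled >= 0 & filled <= 48))
  }
})

test_that("a chain with nothing to impute returns its input unchanged", {
  ch <- oks_cohort(120, seed = 58)
  spec <- build_default_spec("score", instrument_sim(oks_spec()), ch, m = 2)
  expect_identical(run_chain(ch, spec, 59), ch)
})

test_that("a single-variable chain equals one direct PMM imputation", {
  amp <- amputed_oks(n = 250, seed = 60,
                     mixture = load_fixture("oks_unit_mixture"))
  dat <- amp$data
  spec <- build_default_spec("score", instrument_sim(oks_spec()), dat,
                             m = 2, by_arm = FALSE)
  mdl <- spec$models[[1]]
  got <- run_chain(dat, spec, 61)
  # oracle: replay the chain's RNG protocol by hand for one model
  y <- dat$oks_fu
  X <- data.matrix(dat[, mdl$predictors])
  set.seed(61)
  fill <- sample(y[!is.na(y)], sum(is.na(y)), replace = TRUE)
  want <- impute_pmm(y, X, k = mdl$k)
  expect_equal(got$oks_fu, want)
})

test_that("chained imputation is deterministic and complete", {
  amp <- amputed_oks(n = 250, seed = 62)
  dat <- amp$data
  spec <- build_default_spec("item", instrument_sim(oks_spec()), dat,
                             m = 3, cycles = 3)
  i1 <- generate_imputations(dat, spec, 63)
  i2 <- generate_imputations(dat, spec, 63)
  expect_identical(i1$completions, i2$completions)
  expect_equal(i1$attempted, 3L)
  oks <- oks_spec()
  for (cc in i1$completions) {
    items <- as.matrix(cc[, item_cols(oks, "fu")])
    expect_false(anyNA(items))
    for (j in 1:12) expect_true(all(items[, j] %in% 0:4))
  }
})

test_that("persistent failure aborts the set under the tolerance rule", {
  amp <- amputed_oks(n = 250, seed = 64)
  dat <- amp$data
  spec <- build_default_spec("item", instrument_sim(oks_spec()), dat,
                             m = 4, cycles = 2)
  # force a zero-cell scan failure on every attempt: demand a category
  # that never occurs
  spec$models[[1]]$levels <- 0:5
  spec$fallback_pooled <- FALSE
  out <- generate_imputations(dat, spec, 65)
  expect_true(is_failure(out))
  expect_s3_class(out, "promice_failed_set")
  expect_identical(out$reason, "perfect_prediction")
  expect_gt(out$failure_count, 0.5 * out$attempted)
})

test_that("a failing by-arm set falls back to pooled imputation with arm", {
  amp <- amputed_oks(n = 300, seed = 66,
                     mixture = load_fixture("oks_unit_mixture"))
  dat <- amp$data
  # by-arm subscale imputation whose stratum fit is starved of rows in one
  # arm: drop most of arm 1 to force overfit there
  keep <- c(which(dat$arm == 0), which(dat$arm == 1)[1:12])
  dat2 <- dat[keep, ]
  spec <- build_default_spec("subscale", instrument_sim(oks_spec()), dat2,
                             m = 2, by_arm = TRUE)
  out <- generate_imputations(dat2, spec, 67)
  expect_false(is_failure(out))
  expect_true(out$fallback_used)
})

test_that("default specs encode the covariate and m conventions", {
  amp <- amputed_oks(n = 200, seed = 68)
  dat <- amp$data
  s_score <- build_default_spec("score", instrument_sim(oks_spec()), dat)
  expect_equal(s_score$m, 50L)
  expect_identical(vapply(s_score$models, `[[`, "", "target"), "oks_fu")
  expect_true(s_score$by_arm)
  expect_false("arm" %in% s_score$models[[1]]$predictors)
  expect_true(all(c("oks_base", "age", "sex", "height", "asa",
                    "centre_size") %in% s_score$models[[1]]$predictors))

  s_item <- build_default_spec("item", instrument_sim(oks_spec()), dat,
                               p = 0.2, base_case_n = 1030)
  expect_equal(s_item$m, 20L)                 # m = 100 * p below base case
  expect_false(s_item$by_arm)                 # 12 items: pooled compromise
  expect_true("arm" %in% s_item$models[[1]]$predictors)
  expect_true(all(c("oks_pain_base", "oks_fn_base") %in%
                  s_item$models[[1]]$predictors))
  expect_equal(length(s_item$models), 12L)
  expect_false("oks_fu_i1" %in% s_item$models[[1]]$predictors)

  s_exp <- build_default_spec("item", instrument_sim(oks_spec()), dat,
                              p = 0.2, exploratory = TRUE)
  expect_equal(s_exp$m, 10L)
  full <- build_default_spec("item", instrument_sim(oks_spec()), dat,
                             p = 0.2, base_case_n = nrow(dat))
  expect_equal(full$m, 50L)
  # five-item instruments impute by arm even at item level
  ampe <- ampute(eq5d_cohort(200),
                 amputation_config("eq5d", 0.2,
                                   load_fixture("eq5d_observed_mixture")), 69)
  s_eq <- build_default_spec("item",
                             instrument_sim(eq5d_spec(), orientation = -1),
                             ampe$data, p = 0.2)
  expect_true(s_eq$by_arm)
  expect_error(build_default_spec("subscale",
                                  instrument_sim(eq5d_spec(),
                                                 orientation = -1),
                                  ampe$data), "no subscales")
})

test_that("pooling recovers the complete-data estimate when nothing is missing", {
  ch <- oks_cohort(150, seed = 70)
  spec <- build_default_spec("score", instrument_sim(oks_spec()), ch, m = 3)
  imps <- generate_imputations(ch, spec, 71)
  ests <- vapply(imps$completions, function(cc)
    fit_analysis_model(cc, "oks_fu")$effect, 0)
  ses <- vapply(imps$completions, function(cc)
    fit_analysis_model(cc, "oks_fu")$se, 0)
  pooled <- rubin_pool(ests, ses)
  direct <- fit_analysis_model(ch, "oks_fu")
  expect_equal(pooled$point, direct$effect)
  expect_equal(pooled$B, 0)
  expect_equal(pooled$se, direct$se)
})
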