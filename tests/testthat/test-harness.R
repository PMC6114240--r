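fake_records <- function(errors, truth = 10, estimand = "overall") {
  n <- length(errors)
  rbind(
    data.frame(iteration = seq_len(n), method = "truth", estimand = estimand,
               estimate = truth, se = 0.1, n_used = 100, m_used = NA),
    data.frame(iteration = seq_len(n), method = "mi_score",
               estimand = estimand, estimate = truth + errors, se = 0.2,
               n_used = 100, m_used = 5))
}

test_that("performance metrics match hand computation", {
  p1 <- compute_performance(fake_records(c(1, -1)))
  expect_equal(p1$rmse, 1)
  expect_equal(p1$mae, 1)
  expect_equal(p1$bias, 0)
  p2 <- compute_performance(fake_records(c(0, 2)))
  expect_equal(p2$rmse, sqrt(2))
  expect_equal(p2$mae, 1)
  expect_equal(p2$bias, 1)
  # zero error everywhere
  p3 <- compute_performance(fake_records(rep(0, 5)))
  expect_equal(p3$rmse, 0)
  expect_equal(p3$mae, 0)
})

test_that("RMSE decomposes into bias and error variance", {
  set.seed(91)
  err <- rnorm(200, mean = 0.3, sd = 1.2)
  p <- compute_performance(fake_records(err))
  n <- length(err)
  expect_equal(p$rmse^2, p$bias^2 + var(err) * (n - 1) / n,
               tolerance = 1e-10)
  expect_gte(p$rmse, p$mae)
})

test_that("mismatched iteration sets are an input error", {
  rec <- fake_records(c(1, -1))
  rec <- rec[!(rec$method == "truth" & rec$iteration == 2), ]
  expect_error(compute_performance(rec), "mismatched")
})

test_that("iterations are deterministic and their truth matches a direct refit", {
  ch <- oks_cohort(600, seed = 92)
  scn <- scenario(instrument_sim(oks_spec()),
                  load_fixture("oks_observed_mixture"), p = 0.2, n = 200,
                  methods = c("cca", "mi_score"), m = 3, master_seed = 93)
  r1 <- run_iteration(scn, ch, 1001L)
  r2 <- run_iteration(scn, ch, 1001L)
  expect_identical(r1$records, r2$records)
  expect_true(r1$valid)
  sub <- subsample(ch, 200, derive_seed(1001L, 1L))
  direct <- fit_analysis_model(sub, "oks_fu")
  tr <- r1$records[r1$records$method == "truth" &
                   r1$records$estimand == "treatment_effect", ]
  expect_equal(tr$estimate, direct$effect)
  expect_equal(tr$se, direct$se)
})

test_that("truth is invariant to the amputation settings", {
  ch <- oks_cohort(600, seed = 94)
  mk <- function(p) scenario(instrument_sim(oks_spec()),
                             load_fixture("oks_observed_mixture"), p = p,
                             n = 200, methods = "cca", master_seed = 95)
  t1 <- run_iteration(mk(0.05), ch, 7L)$records
  t2 <- run_iteration(mk(0.40), ch, 7L)$records
  expect_identical(t1[t1$method == "truth", ], t2[t2$method == "truth", ])
})

test_that("a CCA-only scenario never skips and stops at its target", {
  ch <- oks_cohort(400, seed = 96)
  scn <- scenario(instrument_sim(oks_spec()),
                  load_fixture("oks_observed_mixture"), p = 0.2, n = 150,
                  methods = "cca", n_valid_target = 4, master_seed = 97)
  sim <- run_scenario(scn, ch)
  expect_equal(sim$valid_n, 4L)
  expect_equal(sim$attempted, 4L)
  expect_false(sim$insufficient)
  perf <- compute_performance(sim)
  expect_true(all(perf$method == "cca"))
  expect_equal(sort(unique(perf$estimand)),
               c("arm0", "arm1", "overall", "treatment_effect"))
})

test_that("persistent convergence failure trips the cap and the flag", {
  ch <- oks_cohort(200, seed = 98)
  scn <- scenario(instrument_sim(oks_spec()),
                  load_fixture("oks_observed_mixture"), p = 0.2, n = 30,
                  methods = "mi_item_ologit", n_valid_target = 2,
                  attempt_cap_multiplier = 2, master_seed = 99,
                  exploratory = TRUE, cycles = 2)
  # n = 30 leaves fewer observed rows than model parameters: every chain
  # fails with an overfit/perfect-prediction reason
  sim <- run_scenario(scn, ch)
  expect_true(sim$insufficient)
  expect_equal(sim$attempted, 4L)
  expect_equal(sim$valid_n, 0L)
  cs <- sim$chain_stats$mi_item_ologit
  expect_equal(unname(cs["failed"] / cs["attempted"]), 1)
})

test_that("the report grid carries one row per scenario-method-estimand", {
  ch <- oks_cohort(500, seed = 100)
  sims <- list()
  for (p in c(0.1, 0.3)) for (n in c(120, 250)) {
    scn <- scenario(instrument_sim(oks_spec()),
                    load_fixture("oks_observed_mixture"), p = p, n = n,
                    methods = c("cca", "mi_score"), m = 2,
                    n_valid_target = 2, master_seed = 101)
    sims[[length(sims) + 1]] <- run_scenario(scn, ch)
  }
  grid <- report(sims)
  expect_equal(nrow(grid), 2 * 2 * 2 * 4)   # p x n x method x estimand
  expect_true(all(c("instrument", "n", "p", "rmse", "mae",
                    "convergence_failure_proportion") %in% names(grid)))
  expect_true(all(is.finite(grid$rmse)))
  pdf(NULL)
  expect_silent(plot(grid, estimand = "overall"))
  dev.off()
})

test_that("an empty method list still yields an empty, well-formed report", {
  ch <- oks_cohort(200, seed = 102)
  scn <- scenario(instrument_sim(oks_spec()),
                  load_fixture("oks_observed_mixture"), p = 0.2, n = 100,
                  methods = character(0), n_valid_target = 2,
                  master_seed = 103)
  sim <- run_scenario(scn, ch)
  expect_equal(sim$valid_n, 2L)
  grid <- report(list(sim))
  expect_true(is.data.frame(grid))
})
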