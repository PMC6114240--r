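test_that("sum-rule composite hits its anchors and mean-substitution rule", {
  oks <- oks_spec()
  expect_equal(score_composite(oks, rep(4, 12)), 48)
  expect_equal(score_composite(oks, rep(0, 12)), 0)
  r <- rep(2, 12); r[5] <- NA
  expect_equal(score_composite(oks, r), 24)   # 11 * 2 + mean(2) by hand
  r[c(1, 9)] <- NA                            # 3 missing exceeds tolerance
  expect_true(is.na(score_composite(oks, r)))
  # two missing still scoreable, fractional result kept unrounded
  r2 <- c(4, 3, 3, 2, NA, NA, 4, 1, 0, 2, 3, 4)
  obs <- r2[!is.na(r2)]
  expect_equal(score_composite(oks, r2), 12 * mean(obs))
})

test_that("mean-substitution equals n_items * mean(observed) for any k <= tolerance", {
  oks <- oks_spec()
  set.seed(11)
  for (i in 1:50) {
    r <- sample(0:4, 12, replace = TRUE)
    k <- sample(0:2, 1)
    if (k > 0) r[sample(12, k)] <- NA
    expect_equal(score_composite(oks, r), 12 * mean(r, na.rm = TRUE))
  }
})

test_that("composite is monotone in every item when all observed", {
  oks <- oks_spec()
  set.seed(12)
  for (i in 1:25) {
    r <- sample(0:3, 12, replace = TRUE)
    j <- sample(12, 1)
    r2 <- r; r2[j] <- r[j] + 1
    expect_gt(score_composite(oks, r2), score_composite(oks, r))
  }
})

test_that("malformed responses are rejected", {
  oks <- oks_spec()
  expect_error(score_composite(oks, rep(2, 11)), "12")
  expect_error(score_composite(oks, c(rep(2, 11), 7)), "not admissible")
})

test_that("subscales score independently of the composite", {
  oks <- oks_spec()
  r <- c(4, 3, 2, 1, 0, 4, 3, 2, 1, 0, 4, 3)
  sc <- score_subscales(oks, r)
  expect_equal(unname(sc[1, "pain"] + sc[1, "fn"]), score_composite(oks, r))
  # whole pain subscale missing: pain undefined, function defined
  r2 <- r; r2[1:7] <- NA
  sc2 <- score_subscales(oks, r2)
  expect_true(is.na(sc2[1, "pain"]))
  expect_equal(unname(sc2[1, "fn"]), sum(r[8:12]))
  # unit nonresponse: both undefined
  sc3 <- score_subscales(oks, rep(NA, 12))
  expect_true(all(is.na(sc3)))
  # one missing pain item tolerated, two not
  r4 <- r; r4[2] <- NA
  expect_false(is.na(score_subscales(oks, r4)[1, "pain"]))
  r4[3] <- NA
  expect_true(is.na(score_subscales(oks, r4)[1, "pain"]))
})

test_that("utility scoring matches the additive tariff by hand", {
  vs <- default_tariff()
  expect_equal(score_eq5d(c(1, 1, 1, 1, 1), vs), 1.0)
  # one dimension at level 2: anchor - constant - that decrement
  expect_equal(score_eq5d(c(1, 1, 1, 1, 2), vs), 1 - 0.081 - 0.071)
  expect_equal(score_eq5d(c(2, 1, 1, 1, 1), vs), 1 - 0.081 - 0.069)
  # worst state: constant + all level-3 decrements + worst-level term
  worst <- 1 - 0.081 - (0.314 + 0.214 + 0.094 + 0.386 + 0.236) - 0.269
  expect_equal(score_eq5d(c(3, 3, 3, 3, 3), vs), worst)
  expect_true(is.na(score_eq5d(c(1, NA, 1, 1, 1), vs)))
  expect_error(score_eq5d(c(1, 1, 1, 1, 4), vs), "1..3")
  expect_error(eq5d_value_set(-0.1, matrix(0.1, 5, 2), 0.2), ">= 0")
})

test_that("norm-based scoring standardises its reference sample to 50/10", {
  sp <- sf12_spec()
  set.seed(31)
  ref <- sapply(sp$item_levels, function(L) sample.int(L, 400, replace = TRUE))
  model <- calibrate_norm_model(sp$norm_model, ref)
  sc <- score_normed(model, ref)
  expect_equal(unname(colMeans(sc)), c(50, 50), tolerance = 1e-8)
  expect_equal(unname(apply(sc, 2, sd)), c(10, 10), tolerance = 1e-8)
  # any missing item leaves both components undefined
  r <- ref[1, ]; r[4] <- NA
  expect_true(all(is.na(score_normed(model, r))))
  # a response one reference-sd above the mean weighted sum scores 60
  w <- model$weights[, "pcs"]
  x <- colMeans(ref) + model$reference_sd["pcs"] * w / sum(w^2)
  expect_equal(unname(score_normed(model, x)[1, "pcs"]), 60)
  expect_error(score_normed(sf12_spec()$norm_model, ref), "not calibrated")
})

test_that("pattern classification partitions respondents exhaustively", {
  expect_identical(classify_pattern(rep(NA, 12))$type, "unit_nonresponse")
  expect_identical(classify_pattern(rep(1, 12))$type, "complete")
  r <- rep(1, 12); r[7] <- NA
  cl <- classify_pattern(r)
  expect_identical(cl$type, "item_nonresponse")
  expect_identical(cl$items, 7L)
  set.seed(41)
  m <- matrix(sample(c(0:4, NA), 600, replace = TRUE), ncol = 12)
  types <- classify_pattern(m)
  expect_true(all(types %in% c("complete", "unit_nonresponse",
                               "item_nonresponse")))
  nmiss <- rowSums(is.na(m))
  expect_identical(types == "complete", nmiss == 0L)
  expect_identical(types == "unit_nonresponse", nmiss == 12L)
  lab <- classify_pattern_labels(m)
  expect_identical(lab[nmiss == 0L][1], "complete")
  i <- which(nmiss == 1L)[1]
  expect_identical(lab[i], paste0("item:", which(is.na(m[i, ]))))
})
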