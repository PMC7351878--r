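test_that("a 2x2 collapse recovers the closed-form log odds ratio", {
  a <- 18; b <- 7; c <- 6; d <- 19     # exposed/unexposed x outcome cells
  x <- rep(c(1, 1, 0, 0), c(a, b, c, d))
  y <- rep(c(1, 0, 1, 0), c(a, b, c, d))
  fit <- fit_binary_glm(x, y, unit_scale = 1)
  expect_equal(log(fit$odds_ratio), log(a * d / (b * c)), tolerance = 1e-6)
  expect_false(fit$separation)
})

test_that("a null predictor gives an OR interval covering 1", {
  for (seed in c(2, 5, 8)) {
    set.seed(seed)
    x <- rnorm(500)
    y <- rbinom(500, 1, 0.4)
    fit <- fit_binary_glm(x, y)
    expect_lt(fit$or_conf_low, 1)
    expect_gt(fit$or_conf_high, 1)
  }
})

test_that("AUC follows concordant-pair counting", {
  expect_identical(roc_curve_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_curve_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  set.seed(4)
  s <- sample(seq(0.01, 1, by = 0.01), 30)   # tie-free scores
  l <- rbinom(30, 1, 0.5)
  if (length(unique(l)) == 2L) {
    expect_equal(roc_curve_auc(s, l)$auc, pair_count_auc(s, l))
    # antisymmetry under score negation
    expect_equal(roc_curve_auc(s, l)$auc + roc_curve_auc(-s, l)$auc, 1)
  }
})

test_that("AUC equals the rank-sum U over n1*n2 on tie-free data", {
  set.seed(11)
  a <- rnorm(15, 1)            # cases
  b <- rnorm(12)               # controls
  u <- rank_sum_test(a, b)$statistic
  auc <- roc_curve_auc(c(a, b), rep(c(1, 0), c(15, 12)))$auc
  expect_equal(auc, u / (15 * 12), tolerance = 1e-12)
})

test_that("ROC requires both classes and reports the discrimination band", {
  expect_error(roc_curve_auc(1:5, rep(1, 5)), "both")
  r <- roc_curve_auc(c(1, 2, 3, 4, 5, 6), c(0, 1, 0, 1, 1, 1))
  expect_true(r$band %in% c("weak", "good", "very good"))
  expect_lte(r$conf_low, r$auc)
  expect_gte(r$conf_high, r$auc)
})

test_that("spline partial functions bracket their estimate pointwise", {
  set.seed(3)
  x <- runif(200, -2, 2)
  y <- rbinom(200, 1, plogis(x - 0.5 * x^2))
  fit <- fit_binary_glm(x, y, smooth_df = 3)
  expect_true(all(fit$partial$conf_low <= fit$partial$log_odds))
  expect_true(all(fit$partial$conf_high >= fit$partial$log_odds))
  # the partial function is anchored at the reference (median) point
  anchor <- which.min(abs(fit$partial$x - median(x)))
  expect_lt(abs(fit$partial$log_odds[anchor]), 0.15)
})

test_that("perfect separation is flagged with an unbounded interval", {
  x <- c(rep(0, 12), rep(5, 12))
  y <- c(rep(0, 12), rep(1, 12))
  fit <- suppressWarnings(fit_binary_glm(x, y))
  expect_true(fit$separation)
  expect_identical(fit$or_conf_high, Inf)
  expect_identical(fit$auc$auc, 1)
})

test_that("simulated negative morphology coupling yields OR below 1", {
  co <- generate_cohort(cohort_config(n_patients = 300, dropout_rate = 0,
                                      seed = 19))
  heavy <- co$patients$injection_count >= 8
  fit <- fit_binary_glm(co$patients$fd_baseline, heavy, unit_scale = 0.01)
  expect_lt(fit$odds_ratio, 1)
  expect_gt(fit$auc$auc, 0.7)
})
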