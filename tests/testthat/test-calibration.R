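test_that("AUC equals the Mann-Whitney pair probability and is rank invariant", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  ## perfect separation
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.7, 0.9)), 1.0)
  ## no-signal null
  set.seed(1)
  y <- rbinom(10000, 1, 0.3)
  p <- runif(10000)
  expect_lt(abs(roc_auc(y, p) - 0.5), 0.02)
  ## invariance under a strictly monotone transform
  expect_equal(roc_auc(y, p), roc_auc(y, qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))))
  expect_error(roc_auc(rep(1, 5), runif(5)), "class")
})

test_that("the Hosmer-Lemeshow statistic vanishes under exact group calibration", {
  ## blocks with observed event counts exactly matching expectations
  probs <- seq(0.05, 0.5, by = 0.05)
  y <- unlist(lapply(probs, function(v) rep(c(1, 0), c(round(100 * v), 100 - round(100 * v)))))
  p <- rep(probs, each = 100)
  hl <- hosmer_lemeshow(y, p)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_gte(hl$df, 1)
  expect_true(hl$statistic >= 0)
})

test_that("weak calibration indices carry the constructed sign conventions", {
  set.seed(12)
  n <- 100000
  x <- rnorm(n)
  p <- plogis(-2 + 0.9 * x)
  y <- rbinom(n, 1, p)
  wc <- weak_calibration(y, p)
  expect_lt(abs(wc$citl), 0.02)
  expect_lt(abs(wc$slope - 1), 0.02)
  expect_lt(abs(wc$eo_ratio - 1), 0.02)
  ## +0.5 logit shift in the predictions pushes CITL to -0.5
  p_shift <- plogis(qlogis(p) + 0.5)
  expect_lt(abs(weak_calibration(y, p_shift)$citl - (-0.5)), 0.05)
  ## halving the logits doubles the recalibration slope
  p_half <- plogis(qlogis(p) / 2)
  expect_lt(abs(weak_calibration(y, p_half)$slope - 2), 0.1)
  ## training-sample E:O of a fitted logit with intercept is exactly 1
  f <- glm(y ~ x, family = binomial())
  expect_equal(sum(fitted(f)) / sum(y), 1, tolerance = 1e-8)
})

test_that("binned residual bounds follow the binomial formula and partition the sample", {
  ## direct substitution: p = 0.5, n = 100 in a bin gives bound 0.1
  y <- rep(c(0, 1), 50)
  p <- rep(0.5, 100)
  br <- binned_residuals(y, p)
  expect_equal(br$bins$bound, 2 * sqrt(0.25 / 100))
  expect_equal(br$bins$n_in_bin, 100L)
  ## constant fitted value collapses to one effective bin
  expect_equal(nrow(br$bins), 1L)
  expect_equal(br$bins$mean_residual, mean(y) - 0.5)
  ## bins partition the sample
  set.seed(3)
  p2 <- runif(1000)
  y2 <- rbinom(1000, 1, p2)
  br2 <- binned_residuals(y2, p2)
  expect_equal(sum(br2$bins$n_in_bin), 1000L)
  ## bounds shrink as 1/sqrt(n) within a bin
  br_small <- binned_residuals(y2[1:250], p2[1:250], n_bins = 5)
  br_large <- binned_residuals(rep(y2, 4), rep(p2, 4), n_bins = 5)
  expect_lt(mean(br_large$bins$bound), mean(br_small$bins$bound))
})

test_that("the calibration belt rejects degenerate input and selects a degree of at least 2", {
  expect_error(calibration_belt(rbinom(200, 1, 0.5), rep(0.5, 200)), "degenerate|constant")
  set.seed(21)
  x <- rnorm(5000)
  p <- plogis(-1 + x)
  y <- rbinom(5000, 1, p)
  cb <- calibration_belt(y, p)
  expect_gte(cb$degree, 2)
  expect_true(all(c("p_grid", "fitted", "lower", "upper") %in% names(cb$belt)))
  expect_true(all(cb$belt$lower <= cb$belt$upper))
})

test_that("cross-validated shrinkage is deterministic and detects overfitting", {
  tab <- small_cohort()$table
  spec <- model_spec("logit", covariates = c("age", "severity"))
  a <- cv_shrinkage(tab, spec, k = 5, reps = 2, seed = 42)
  b <- cv_shrinkage(tab, spec, k = 5, reps = 2, seed = 42)
  expect_identical(a, b)
  ## 100 pure-noise covariates on 500 rows overfit badly
  set.seed(17)
  noise <- as.data.frame(matrix(rnorm(500 * 100), 500, 100))
  noise$died <- rbinom(500, 1, 0.3)
  spec_n <- model_spec("logit", covariates = paste0("V", 1:100))
  ov <- suppressWarnings(cv_shrinkage(noise, spec_n, k = 10, reps = 1, seed = 1))
  expect_gt(ov$shrink_out, 5)
  ## a well-specified moderate model barely overfits
  ok <- cv_shrinkage(default_cohort()$table,
                     model_spec("logit", covariates = c("age", "severity", "ventilated")),
                     k = 10, reps = 1, seed = 2)
  expect_lt(abs(ok$overfit_pct), 5)
})

test_that("development/validation splitting is seeded and balanced", {
  tab <- small_cohort()$table
  spec <- model_spec("logit", covariates = c("age", "severity"))
  r1 <- dev_val_report(tab, spec, seed = 7)
  r2 <- dev_val_report(tab, spec, seed = 7)
  expect_equal(r1$development, r2$development)
  expect_equal(r1$development$n + r1$validation$n, nrow(tab))
  expect_equal(r1$development$n, nrow(tab) / 2)
  ## development-half indices are self-calibrated by construction
  expect_lt(abs(r1$development$slope - 1), 1e-6)
  expect_lt(abs(r1$development$eo_ratio - 1), 1e-6)
})

test_that("limits of agreement reduce to closed forms", {
  p <- runif(50)
  expect_equal(loa_summary(p, p), list(mean_diff = 0, loa_lower = 0, loa_upper = 0))
  set.seed(14)
  d <- rnorm(100000, 0.01, 0.001)
  l <- loa_summary(d, rep(0, length(d)))
  expect_lt(abs(l$loa_lower - 0.00804) / 0.00804, 0.10)
  expect_lt(abs(l$loa_upper - 0.01196) / 0.01196, 0.10)
  expect_error(loa_summary(1:3 / 10, 1:4 / 10), "length")
})
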