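test_that("logit slope on a 2x2 table equals the log odds ratio", {
  d <- data.frame(
    exposed = rep(c(1, 1, 0, 0), times = c(10, 40, 20, 30)),
    died = rep(c(1, 0, 1, 0), times = c(10, 40, 20, 30)))
  f <- fit_binary(d, model_spec("logit", covariates = "exposed"))
  expect_equal(unname(f$coefficients["exposed"]),
               log((10 * 30) / (40 * 20)), tolerance = 1e-7)
  expect_equal(round(unname(f$coefficients["exposed"]), 4), -0.9808)
})

test_that("intercept-only linear fit returns the outcome mean", {
  tab <- small_cohort()$table
  f <- fit_binary(tab, model_spec("linear", covariates = character(0)))
  expect_equal(unname(f$coefficients["(Intercept)"]), mean(tab$died))
  expect_equal(unique(round(f$fitted, 12)), round(mean(tab$died), 12))
})

test_that("information criteria match their closed forms on a small fixture", {
  d <- data.frame(x = c(0.1, 0.4, -1, 2, 0.3, -0.2, 1.1, -1.4, 0.6, 0),
                  died = c(1, 0, 0, 1, 1, 0, 1, 0, 1, 0))
  f <- fit_binary(d, model_spec("logit", covariates = "x"))
  k <- length(f$coefficients)
  expect_equal(f$aic, -2 * f$loglik + 2 * k)
  expect_equal(f$bic, -2 * f$loglik + k * log(f$n_used))
  expect_equal(f$n_used, 10L)
  ## vcov symmetric positive semidefinite
  expect_equal(f$vcov, t(f$vcov))
  expect_true(all(eigen(f$vcov, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
})

test_that("perfectly predicted sites are dropped from fixed-effects fits and recorded", {
  tab <- small_cohort()$table
  ## force one site to have no deaths
  tab$died[tab$site_id == "s001"] <- 0L
  f <- fit_binary(tab, model_spec("logit", covariates = c("age", "severity"),
                                  site_fixed_effects = TRUE))
  expect_true("s001" %in% f$dropped_sites)
  expect_lt(f$n_used, nrow(tab))
  expect_false(any(grepl("s001", names(f$coefficients))))
})

test_that("separation is raised explicitly rather than returned as a huge coefficient", {
  set.seed(4)
  x <- rnorm(200)
  d <- data.frame(x = x, died = as.integer(x > 0))
  f <- suppressWarnings(stats::glm(died ~ x, data = d, family = stats::binomial()))
  expect_error(check_separation(f), "separation")
})

test_that("the discriminant transform preserves the marginal and keeps K above 4", {
  tab <- small_cohort()$table
  ## intercept-only: transformed fitted probability equals the outcome mean
  f0 <- fit_binary(tab, model_spec("linear", covariates = character(0)))
  t0 <- lpm_to_logit(f0, tab)
  expect_equal(unique(round(t0$fitted, 10)), round(mean(tab$died), 10))
  ## K = N/RSS >= 4 since the mean squared residual of an LPM is <= 1/4
  f1 <- fit_binary(tab, model_spec("linear", covariates = default_terms()))
  t1 <- lpm_to_logit(f1, tab)
  expect_gte(t1$K, 4)
  expect_gte(t0$K, 4)
  expect_true(all(t1$fitted > 0 & t1$fitted < 1))
})

test_that("unit-interval restriction counts and removes out-of-range predictions", {
  fake <- structure(list(link = "linear", fitted = c(-0.1, 0.5, 1.2)),
                    class = "fit_result")
  tab <- data.frame(a = 1:3)
  r <- restrict_unit_interval(fake, tab)
  expect_equal(r$n_below0, 1L)
  expect_equal(r$n_above1, 1L)
  expect_equal(nrow(r$table), 1L)
  expect_equal(r$fitted, 0.5)
  ## no-op case
  fake2 <- structure(list(link = "linear", fitted = c(0.2, 0.8)),
                     class = "fit_result")
  r2 <- restrict_unit_interval(fake2, data.frame(a = 1:2))
  expect_equal(r2$n_below0 + r2$n_above1, 0L)
  expect_equal(nrow(r2$table), 2L)
  ## LPM on a default synthetic cohort always produces out-of-range rows
  tabd <- default_cohort()$table
  fl <- fit_binary(tabd, model_spec("linear", covariates = default_terms()))
  rl <- restrict_unit_interval(fl, tabd)
  expect_gt(rl$n_below0 + rl$n_above1, 0)
})

test_that("standardized coefficients are invariant to covariate rescaling", {
  tab <- small_cohort()$table
  f <- fit_binary(tab, model_spec("logit", covariates = c("age", "severity")))
  s <- standardize_xy(f)
  tab2 <- tab
  tab2$age <- tab2$age * 10
  f2 <- fit_binary(tab2, model_spec("logit", covariates = c("age", "severity")))
  s2 <- standardize_xy(f2)
  expect_equal(s["age"], s2["age"], tolerance = 1e-8)
  expect_equal(s["severity"], s2["severity"], tolerance = 1e-8)
})

test_that("standardized-coefficient comparison recovers constructed slopes", {
  a <- c(0.2, -0.4, 0.9, 1.4, -0.8, 0.1, 0.6, -1.2)
  ## identity (suppress lm's benign perfect-fit warning)
  id <- suppressWarnings(compare_standardized(a, a))
  expect_equal(id$slope, 1, tolerance = 1e-12)
  expect_true(id$ci[1] <= 1 && 1 <= id$ci[2])
  ## constructed slope of 2
  set.seed(8)
  b <- 2 * a + rnorm(length(a), 0, 0.01)
  cs <- compare_standardized(a, b)
  expect_lt(abs(cs$slope - 2), 2 * cs$se)
  expect_error(compare_standardized(a, b[-1]), "length")
})
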