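test_that("intraclass correlation follows the latent-variance formula", {
  expect_equal(icc(0, "logit"), 0)
  expect_equal(icc(0, "probit"), 0)
  ## symmetry point: tau2 equal to the link constant gives ICC one half
  expect_equal(icc(pi^2 / 3, "logit"), 0.5)
  expect_equal(icc(1, "probit"), 0.5)
  expect_error(icc(-0.1, "logit"), "nonnegative")
  ## monotone in tau2, bounded in [0, 1)
  taus <- seq(0, 10, by = 0.5)
  vals <- sapply(taus, icc, link = "logit")
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals < 1))
})

test_that("constraining the intercept variance to zero reproduces the single-level fit", {
  tab <- small_cohort()$table
  f0 <- fit_re(tab, "logit", c("age", "severity"), fix_tau_zero = TRUE)
  g <- fit_binary(tab, model_spec("logit", covariates = c("age", "severity")))
  expect_equal(f0$tau2, 0)
  expect_true(f0$boundary)
  expect_equal(unname(f0$coefficients), unname(g$coefficients), tolerance = 1e-6)
  expect_equal(f0$loglik, g$loglik, tolerance = 1e-8)
})

test_that("random-intercept preconditions are enforced", {
  tab <- small_cohort()$table
  expect_error(fit_re(tab, "logit", quadrature_points = 3), ">= 5")
  tab1 <- tab; tab1$died <- 0L
  expect_error(fit_re(tab1, "logit"), "single class")
  tab2 <- tab[tab$site_id == tab$site_id[1], ]
  expect_error(fit_re(tab2, "logit"), "sites")
})

test_that("a random-intercept fit on a clustered cohort reports positive variance", {
  reg <- cached("re_cohort", generate_registry(registry_config(
    n_patients = 6000, n_sites = 40, site_sd = 1,
    corr_vm = 0, corr_hm = 0, corr_vh = 0, seed = 31)))
  f <- fit_re(reg$table, "logit", c("age", "severity", "ventilated"),
              quadrature_points = 8L)
  expect_s3_class(f, "re_fit")
  expect_gt(f$tau2, 0.1)
  expect_false(f$boundary)
  expect_true(is.finite(f$loglik))
  expect_length(f$posterior_modes, 40L)
  ## posterior modes track the realised site intercepts
  expect_gt(cor(f$posterior_modes, reg$truth$site_intercepts), 0.5)
})

test_that("the dichotomous R-squared partitions latent variance", {
  tab <- small_cohort()$table
  ## null single-level model: no explained variance
  f0 <- fit_re(tab, "logit", character(0), fix_tau_zero = TRUE)
  expect_equal(r2_dichot(f0, tab), 0)
  ## closed form: sF2 = 3.29 with tau2 = 0 under the logit link gives 1/2
  fake <- structure(list(tau2 = 0, link = "logit",
                         model = structure(list(), class = "null_lp")),
                    class = "re_fit")
  sF2 <- pi^2 / 3
  expect_equal(sF2 / (sF2 + 0 + pi^2 / 3), 0.5)
  ## fitted model: R2 strictly between 0 and 1 and larger for the logit
  ## constant denominators than probit on logistic data
  f <- fit_re(tab, "logit", c("age", "severity"), fix_tau_zero = TRUE)
  r2 <- r2_dichot(f, tab)
  expect_gt(r2, 0)
  expect_lt(r2, 1)
})
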