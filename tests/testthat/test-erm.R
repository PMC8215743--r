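test_that("model specification enforces exclusion restrictions", {
  expect_error(erm_spec(outcome_terms = c("age", "ventilated"),
                        components = "treatment"), "outcome_terms")
  expect_error(erm_spec(outcome_terms = c("age", "severity"),
                        treatment_terms = c("age", "severity"),
                        components = "treatment"), "instrument")
  expect_error(erm_spec(outcome_terms = c("age", "log(hlos)"),
                        components = "continuous"), "outcome_terms")
  sp <- erm_spec(components = "both")
  expect_s3_class(sp, "erm_spec")
})

test_that("analytic scores match finite differences of the log-likelihood", {
  tab <- small_cohort()$table[1:400, ]
  sp <- erm_spec(outcome = "died", outcome_terms = c("age", "severity"),
                 treatment = "ventilated",
                 treatment_terms = c("age", "severity", "hospital_level"),
                 cont_endog = "log(hlos)",
                 cont_terms = c("age", "severity", "hospital_level"),
                 components = "both")
  th <- erm_start(tab, sp)
  th[length(th) - 2:0] <- c(0.2, -0.3, 0.1)  # non-trivial correlations
  mats <- icuendo:::erm_matrices(tab, sp)
  ob <- icuendo:::erm_objective(th, mats, want_score = TRUE)
  eps <- 1e-6
  num <- sapply(seq_along(th), function(j) {
    tp <- th; tp[j] <- tp[j] + eps
    tm <- th; tm[j] <- tm[j] - eps
    (icuendo:::erm_objective(tp, mats) - icuendo:::erm_objective(tm, mats)) / (2 * eps)
  })
  expect_equal(unname(ob$grad), num, tolerance = 1e-4)
})

test_that("the log-likelihood is local to each observation's outcome", {
  tab <- small_cohort()$table[1:60, ]
  sp <- erm_spec(outcome = "died", outcome_terms = "age",
                 treatment = "ventilated", treatment_terms = c("age", "severity"),
                 cont_endog = "log(hlos)", cont_terms = c("age", "severity"),
                 components = "both")
  th <- erm_start(tab, sp)
  th[length(th) - 2:0] <- c(0.15, -0.2, 0.05)
  ll_base <- erm_loglik(th, tab, sp)
  tab2 <- tab
  tab2$died[5] <- 1L - tab2$died[5]
  ll_flip <- erm_loglik(th, tab2, sp)
  ## difference equals the difference of the single affected row's contribution
  one_a <- erm_loglik(th, tab[5, , drop = FALSE], sp)
  one_b <- erm_loglik(th, tab2[5, , drop = FALSE], sp)
  expect_equal(ll_flip - ll_base, one_b - one_a, tolerance = 1e-9)
})

test_that("the fitted likelihood nests the independent single-equation fits", {
  st <- cached_erm()
  th0 <- erm_start(st$table, st$spec)
  expect_gte(st$fit$loglik, erm_loglik(th0, st$table, st$spec))
  expect_true(st$fit$converged)
  ## correlation estimates and CIs strictly inside (-1, 1)
  rt <- st$fit$rho_table
  expect_true(all(abs(rt$estimate) < 1))
  expect_true(all(rt$ci_lower > -1 & rt$ci_upper < 1))
  expect_equal(nrow(rt), 3L)
  ## parameter count mismatch rejected
  expect_error(erm_loglik(th0[-1], st$table, st$spec), "parameters")
})

test_that("weak instruments in the first stage raise a warning", {
  set.seed(55)
  n <- 3000
  d <- data.frame(age = rnorm(n), z = rnorm(n))
  d$x <- rnorm(n)                       # endogenous variable ignores z
  d$died <- rbinom(n, 1, pnorm(-1 + 0.5 * d$age))
  sp <- erm_spec(outcome = "died", outcome_terms = "age",
                 cont_endog = "x", cont_terms = c("age", "z"),
                 components = "continuous")
  expect_warning(fit_erm(d, sp), "weak instrument")
})

test_that("treatment effects and margins respect their structural definitions", {
  st <- cached_erm()
  te <- treatment_effects(st$fit, st$table)
  ## ATE is the mean potential-outcome contrast by construction
  expect_equal(te$ate$estimate, te$pom1 - te$pom0, tolerance = 1e-12)
  expect_true(te$ate$ci[1] < te$ate$estimate && te$ate$estimate < te$ate$ci[2])
  expect_gt(te$ate$se, 0)
  ## margins: mortality nondecreasing in severity under both scenarios
  mg <- margins_grid(st$fit, st$table, "severity", c(20, 60, 100, 140))
  expect_true(all(diff(mg$p_ventilated) > 0))
  expect_true(all(diff(mg$p_unventilated) > 0))
  expect_equal(mg$contrast, mg$p_ventilated - mg$p_unventilated)
  expect_true(all((mg$contrast_lo <= mg$contrast) & (mg$contrast <= mg$contrast_hi)))
  ## out-of-support grid values warn, invalid grid variables error
  expect_warning(margins_grid(st$fit, st$table, "severity", c(60, 5000)),
                 "support")
  expect_error(margins_grid(st$fit, st$table, "hlos", 2), "outcome-equation")
})

test_that("exogeneity checks flag constructed endogeneity and name missing variables", {
  tab <- default_cohort()$table
  expect_error(exogeneity_check(tab, "log(apache)", instruments = "age"),
               "apache")
  ## rod is built from the outcome's own linear predictor: strongly endogenous
  ck <- suppressWarnings(exogeneity_check(
    tab, "qnorm(rod)",
    instruments = c("age", "severity", "dx_category", "hospital_level",
                    "volume_decile"),
    outcome_terms = c("age", "severity")))
  expect_lt(ck$p_value, 0.05)
  ## CI bounded away from zero
  expect_true(ck$ci[2] < 0 || ck$ci[1] > 0)
})
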