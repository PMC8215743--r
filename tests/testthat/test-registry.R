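test_that("generated registries satisfy the structural contract", {
  reg <- small_cohort()
  tab <- reg$table
  expect_named(tab, c("site_id", "hospital_level", "volume_decile", "age",
                      "severity", "dx_category", "ventilated", "hlos",
                      "rod", "died"))
  expect_false(anyNA(tab))
  expect_true(all(tab$hlos > 0))
  expect_true(all(tab$rod > 0 & tab$rod < 1))
  expect_true(all(tab$died %in% 0:1))
  expect_true(all(tab$ventilated %in% 0:1))
  expect_true(all(tab$severity >= 0 & tab$severity <= 299))
  expect_true(all(tab$age >= 16 & tab$age <= 100))
  ## every site populated
  expect_equal(length(unique(tab$site_id)), 12L)
  ## ground truth serialized alongside
  expect_true(all(c("config", "intercepts", "site_intercepts",
                    "latent_correlation") %in% names(reg$truth)))
})

test_that("a fixed seed reproduces the registry bit for bit", {
  cfg <- registry_config(n_patients = 2000, n_sites = 8, seed = 77)
  a <- generate_registry(cfg)
  b <- generate_registry(cfg)
  expect_identical(a$table, b$table)
  c2 <- generate_registry(registry_config(n_patients = 2000, n_sites = 8, seed = 78))
  expect_false(identical(a$table, c2$table))
})

test_that("realized marginals hit the cohort targets at large n", {
  reg <- cached("big100k", generate_registry(
    registry_config(n_patients = 100000, seed = 11)))
  tab <- reg$table
  expect_lt(abs(mean(tab$died) - 0.0882), 0.005)
  expect_lt(abs(mean(tab$ventilated) - 0.437), 0.005)
})

test_that("latent error correlations are reproduced or switched off as configured", {
  ## independence case: all configured correlations zero
  reg0 <- generate_registry(registry_config(
    n_patients = 100000, corr_vm = 0, corr_hm = 0, corr_vh = 0, seed = 5))
  C0 <- cor(reg0$latent[, c("eps_v", "eps_h", "eps_m")])
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.02)
  ## default correlations within Monte-Carlo error of the configuration
  reg <- cached("big100k", generate_registry(
    registry_config(n_patients = 100000, seed = 11)))
  C <- cor(reg$latent[, c("eps_v", "eps_h", "eps_m")])
  se <- 1 / sqrt(100000)
  expect_lt(abs(C["eps_v", "eps_m"] - (-0.248)), 3 * se)
  expect_lt(abs(C["eps_h", "eps_m"] - (-0.315)), 3 * se)
  expect_lt(abs(C["eps_v", "eps_h"] - 0.119), 3 * se)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(registry_config(n_sites = 1), "n_sites")
  expect_error(registry_config(target_mortality = 1.2), "target_mortality")
  ## correlation triple violating positive definiteness
  expect_error(registry_config(corr_vm = 0.9, corr_hm = 0.9, corr_vh = -0.9),
               "positive definite")
  expect_error(registry_config(sigma_h = -1), "sigma_h")
})

test_that("CSV round-trip preserves the registry losslessly", {
  tab <- small_cohort()$table
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_registry(tab, path)
  back <- read_registry(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  ## one-row round trip preserves types
  write_registry(tab[1, ], path)
  one <- read_registry(path)
  expect_equal(as.data.frame(one), as.data.frame(tab[1, ]))
  expect_identical(sapply(one, class), sapply(tab, class))
  ## missing outcome column named in the error
  bad <- tab[, setdiff(names(tab), "died")]
  path2 <- tempfile(fileext = ".csv")
  on.exit(unlink(path2), add = TRUE)
  data.table::fwrite(bad, path2)
  expect_error(suppressWarnings(read_registry(path2)), "died")
})

test_that("counterfactual simulation responds to forced treatment", {
  reg <- default_cohort()
  m1 <- simulate_counterfactual(reg$truth, reg$table, treat = 1, seed = 9)
  m0 <- simulate_counterfactual(reg$truth, reg$table, treat = 0, seed = 9)
  expect_length(m1, nrow(reg$table))
  expect_true(all(m1 %in% 0:1) && all(m0 %in% 0:1))
  ## positive structural treatment effect => higher mortality when all treated
  expect_gt(mean(m1), mean(m0))
})
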