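test_that("a full study run assembles every configured model with failure isolation", {
  tab <- cached("study_tab", generate_registry(
    registry_config(n_patients = 5000, n_sites = 20, seed = 301)))$table
  cfg <- study_config(registry = tab, cv_k = 5L, cv_reps = 1L,
                      cv_models = "logit1", quadrature_points = 5L,
                      erm_continuous = "log(hlos)", seed = 301)
  rep <- cached("study_report", suppressWarnings(run_study(cfg)))
  ## eight base models plus transforms and added-covariate variants
  base <- c("logit1", "logit2", "probit1", "probit2", "lpm1_ldm", "lpm2_ldm",
            "logit3", "probit3", "lpm0", "logit1_loghlos", "logit1_logrod")
  expect_true(all(base %in% names(rep$models)))
  expect_true(validate_report(rep))
  ## per-model calibration columns present for non-failed entries
  ok <- Filter(function(r) is.null(r$failed), rep$models)
  expect_gt(length(ok), 8)
  for (r in ok[intersect(names(ok), base)])
    expect_true(all(c("auc", "citl", "slope", "eo_ratio", "aic", "bic") %in%
                      names(r)) || "auc" %in% names(r))
  ## AIC/BIC ranking covers each converged probability model exactly once
  expect_false(any(duplicated(rep$information_criteria$model)))
  ## endogeneity section carries the correlation table and effects
  e <- rep$endogeneity$loghlos
  expect_null(e$failed)
  expect_equal(nrow(e$rho_table), 3L)
  expect_true(is.finite(e$ate$estimate))
  ## ICC: conditional does not exceed unconditional on the default generator
  expect_lte(rep$icc$logit$conditional, rep$icc$logit$unconditional + 0.02)
})

test_that("study reports are byte-identical across reruns with one seed", {
  tab <- cached("study_tab", generate_registry(
    registry_config(n_patients = 5000, n_sites = 20, seed = 301)))$table
  cfg <- study_config(registry = tab, cv_k = 5L, cv_reps = 1L,
                      cv_models = "logit1", quadrature_points = 5L,
                      erm_continuous = "log(hlos)", seed = 301)
  rep1 <- cached("study_report", suppressWarnings(run_study(cfg)))
  rep2 <- suppressWarnings(run_study(cfg))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(f1, f2)))
  write_study_report(rep1, f1)
  write_study_report(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("report validation names the first structural violation", {
  rep <- cached("study_report", NULL)
  skip_if(is.null(rep), "study report fixture unavailable")
  broken <- rep
  broken$icc <- NULL
  expect_error(validate_report(broken), "icc")
  broken2 <- rep
  broken2$models$logit1$auc <- NULL
  expect_error(validate_report(broken2), "logit1")
  ## the schema document ships with the package
  schema <- system.file("schema", "study_report_schema.json", package = "icuendo")
  expect_true(nzchar(schema))
  parsed <- jsonlite::fromJSON(schema)
  expect_true(all(c("header", "models", "endogeneity") %in%
                    names(parsed$properties)))
})

test_that("user-supplied cohorts are checked before the study starts", {
  tab <- cached("study_tab", generate_registry(
    registry_config(n_patients = 5000, n_sites = 20, seed = 301)))$table
  bad <- tab
  bad$hlos <- NULL
  expect_error(run_study(study_config(registry = bad, seed = 1)), "hlos")
  expect_error(study_config(registry = tab, seed = NULL), "seed")
})
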