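## Orchestration of the full modelling study on a synthetic or user-supplied
## cohort: the eight base models, added-covariate variants, calibration
## reports, standardised-coefficient comparisons, endogeneity analyses and a
## structured, reproducible report.

#' Study configuration
#'
#' @param registry a [registry_config()] (a cohort is generated) or a
#'   registry table.
#' @param base_terms covariate terms of the base mortality models.
#' @param re_terms fixed-effect terms of the random-intercept models (factor
#'   expansions are kept out by default so adaptive quadrature stays fast).
#' @param added_covariates extra covariates scanned one at a time on the
#'   base logit.
#' @param cv_k,cv_reps cross-validation folds and repetitions.
#' @param cv_models models (by report key) to cross-validate.
#' @param quadrature_points adaptive quadrature nodes for the RE models.
#' @param erm_continuous continuous endogenous variables; one extended
#'   probit (with endogenous ventilation) is estimated per entry.
#' @param margins_grid_var,margins_grid_values marginal-effect grid.
#' @param seed master seed (mandatory; all randomness derives from it).
#' @return object of class `study_config`.
#' @export
study_config <- function(registry = registry_config(),
                         base_terms = default_terms(),
                         re_terms = c("age", "severity", "ventilated"),
                         added_covariates = c("log(hlos)", "log(rod)"),
                         cv_k = 10L, cv_reps = 2L,
                         cv_models = c("logit1", "probit1"),
                         quadrature_points = 12L,
                         erm_continuous = c("log(hlos)", "log(rod)"),
                         margins_grid_var = "severity",
                         margins_grid_values = seq(20, 120, by = 25),
                         seed = 1L) {
  if (is.null(seed)) stop_named("a seed is mandatory")
  structure(list(registry = registry, base_terms = base_terms,
                 re_terms = re_terms, added_covariates = added_covariates,
                 cv_k = as.integer(cv_k), cv_reps = as.integer(cv_reps),
                 cv_models = cv_models,
                 quadrature_points = as.integer(quadrature_points),
                 erm_continuous = erm_continuous,
                 margins_grid_var = margins_grid_var,
                 margins_grid_values = margins_grid_values,
                 seed = as.integer(seed)), class = "study_config")
}

try_model <- function(label, expr) {
  tryCatch(expr, error = function(e)
    list(failed = TRUE, model = label, error = conditionMessage(e)))
}

#' Run the full modelling study
#'
#' Fits the eight base mortality models (logit, probit, LPM; vanilla and
#' provider fixed effects; random-intercept logit and probit), the
#' added-covariate logit variants, and the extended probit fits with
#' endogenous ventilation; produces per-model calibration reports,
#' information-criterion ranking, standardised-coefficient comparisons,
#' error-correlation tables, treatment effects and marginal-effect grids.
#' Any single model failure is recorded with a failure marker and does not
#' abort the study. Deterministic given the configuration seed.
#'
#' @param config a [study_config()].
#' @return a `study_report` list.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (inherits(config$registry, "registry_config")) {
    reg <- generate_registry(config$registry)
    table <- reg$table
    truth <- reg$truth
  } else {
    table <- config$registry
    check_registry_columns(table)
    truth <- NULL
  }
  y <- table$died

  specs <- list(
    logit1 = model_spec("logit", covariates = config$base_terms),
    logit2 = model_spec("logit", covariates = config$base_terms,
                        site_fixed_effects = TRUE),
    probit1 = model_spec("probit", covariates = config$base_terms),
    probit2 = model_spec("probit", covariates = config$base_terms,
                         site_fixed_effects = TRUE),
    lpm1 = model_spec("linear", covariates = config$base_terms,
                      robust_se = TRUE),
    lpm2 = model_spec("linear", covariates = config$base_terms,
                      site_fixed_effects = TRUE, robust_se = TRUE))

  fits <- list()
  for (nm in names(specs))
    fits[[nm]] <- try_model(nm, fit_binary(table, specs[[nm]]))

  ## Haggstrom transform of the two LPM fits; unit-interval restriction
  lpm_ldm <- try_model("lpm1_ldm", lpm_to_logit(fits$lpm1, table))
  lpm2_ldm <- try_model("lpm2_ldm", lpm_to_logit(fits$lpm2, table))
  lpm0 <- try_model("lpm0", {
    r <- restrict_unit_interval(fits$lpm1, table)
    refit <- fit_binary(r$table, specs$lpm1)
    list(restriction = r[c("n_below0", "n_above1", "frac_below0", "frac_above1")],
         fit = refit)
  })

  ## random-intercept models
  re_fits <- list(
    logit3 = try_model("logit3", fit_re(table, "logit", config$re_terms,
                                        quadrature_points = config$quadrature_points)),
    probit3 = try_model("probit3", fit_re(table, "probit", config$re_terms,
                                          quadrature_points = config$quadrature_points)))
  re_null <- list(
    logit = try_model("logit3_null", fit_re(table, "logit", character(0),
                                            quadrature_points = config$quadrature_points)),
    probit = try_model("probit3_null", fit_re(table, "probit", character(0),
                                              quadrature_points = config$quadrature_points)))

  icc_tab <- lapply(c(logit = "logit", probit = "probit"), function(lk) {
    fullf <- re_fits[[if (lk == "logit") "logit3" else "probit3"]]
    nullf <- re_null[[lk]]
    list(unconditional = if (is.null(nullf$failed)) icc(nullf$tau2, lk) else NA_real_,
         conditional = if (is.null(fullf$failed)) icc(fullf$tau2, lk) else NA_real_,
         r2_dichot = if (is.null(fullf$failed)) r2_dichot(fullf, table) else NA_real_)
  })

  ## added-covariate logit variants
  added <- list()
  for (v in config$added_covariates) {
    key <- paste0("logit1_", gsub("[^a-z0-9]+", "", tolower(v)))
    added[[key]] <- try_model(key, fit_binary(
      table, model_spec("logit", covariates = c(config$base_terms, v))))
  }

  ## calibration reports for everything with fitted probabilities
  all_fits <- c(fits[c("logit1", "logit2", "probit1", "probit2")],
                list(lpm1_ldm = lpm_ldm, lpm2_ldm = lpm2_ldm), added)
  reports <- lapply(all_fits, function(f) {
    if (!is.null(f$failed)) return(f)
    try_model("calibration", calibration_report(f, y))
  })
  for (nm in names(re_fits)) {
    f <- re_fits[[nm]]
    if (is.null(f$failed)) {
      pf <- as.numeric(stats::fitted(f$model))
      reports[[nm]] <- try_model(nm, calibration_report(
        list(fitted = pf, aic = f$aic, bic = f$bic), y))
    } else reports[[nm]] <- f
  }
  if (is.null(lpm0$failed)) {
    reports$lpm0 <- try_model("lpm0", c(
      calibration_report(lpm0$fit, lpm0$fit$model$model[[1]], belt = FALSE),
      lpm0$restriction))
  } else reports$lpm0 <- lpm0

  ## LPM reports on the raw linear fits (AUC etc. tolerate values outside
  ## (0,1) only through clamping; belt skipped)
  for (nm in c("lpm1", "lpm2")) {
    f <- fits[[nm]]
    if (is.null(f$failed))
      reports[[paste0(nm, "_raw")]] <- try_model(nm, list(
        auc = roc_auc(y, f$fitted), aic = f$aic, bic = f$bic))
  }

  ## information-criterion ranking over converged probability models
  ic <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    if (!is.null(r$failed) || is.null(r$aic)) return(NULL)
    data.frame(model = nm, aic = r$aic, bic = r$bic)
  }))
  if (!is.null(ic)) {
    ic$aic_rank <- rank(ic$aic)
    ic$bic_rank <- rank(ic$bic)
  }

  ## standardised coefficients, logit as comparator
  std <- try_model("standardized", {
    s_logit <- standardize_xy(fits$logit1)
    s_probit <- standardize_xy(fits$probit1)
    s_lpm <- standardize_xy(fits$lpm1)
    out <- list(probit = compare_standardized(s_logit, s_probit)[c("slope", "se", "p_value", "ci")],
                lpm_all_n = compare_standardized(s_logit, s_lpm)[c("slope", "se", "p_value", "ci")])
    if (is.null(lpm0$failed)) {
      s_lpm0 <- standardize_xy(lpm0$fit)
      out$lpm_01 <- compare_standardized(s_logit, s_lpm0)[c("slope", "se", "p_value", "ci")]
    }
    out
  })

  ## limits of agreement: logit vs transformed-LPM probabilities
  loa <- if (is.null(fits$logit1$failed) && is.null(lpm_ldm$failed))
    loa_summary(fits$logit1$fitted, lpm_ldm$fitted) else NULL

  ## cross-validated shrinkage
  cv <- list()
  for (nm in intersect(config$cv_models, names(specs))) {
    cv[[nm]] <- try_model(nm, cv_shrinkage(
      table, specs[[nm]], k = config$cv_k, reps = config$cv_reps,
      seed = substream_seed(config$seed, 10L)))
  }
  devval <- try_model("dev_val", dev_val_report(
    table, specs$logit1, seed = substream_seed(config$seed, 11L)))

  ## endogeneity analyses: extended probit per continuous endogenous variable
  endo <- list()
  for (v in config$erm_continuous) {
    key <- gsub("[^a-z0-9]+", "", tolower(v))
    endo[[key]] <- try_model(key, {
      sp <- erm_spec(outcome = "died", outcome_terms = c("age", "severity"),
                     treatment = "ventilated", cont_endog = v,
                     components = "both")
      f <- fit_erm(table, sp)
      te <- treatment_effects(f, table)
      mg <- margins_grid(f, table, config$margins_grid_var,
                         config$margins_grid_values)
      list(rho_table = f$rho_table, loglik = f$loglik, aic = f$aic,
           bic = f$bic, converged = f$converged,
           ate = te$ate, atet = te$atet, pom0 = te$pom0, pom1 = te$pom1,
           margins = mg)
    })
  }

  report <- list(
    header = list(package = "icuendo",
                  version = as.character(utils::packageVersion("icuendo")),
                  seed = config$seed, n_patients = nrow(table),
                  n_sites = length(unique(table$site_id))),
    models = reports,
    information_criteria = ic,
    icc = icc_tab,
    standardized = std,
    loa = loa,
    cv_shrinkage = cv,
    dev_val = if (is.null(devval$failed))
      devval[c("development", "validation")] else devval,
    endogeneity = endo,
    truth = if (!is.null(truth)) truth["intercepts"] else NULL)
  class(report) <- "study_report"
  report
}

#' Limits-of-agreement summary for two probability vectors
#'
#' @param p_a,p_b equal-length probability vectors.
#' @return list with `mean_diff`, `loa_lower`, `loa_upper`
#'   (mean difference +/- 1.96 SD).
#' @export
loa_summary <- function(p_a, p_b) {
  if (length(p_a) != length(p_b))
    stop_named("probability vectors differ in length (%d vs %d)",
               length(p_a), length(p_b))
  d <- p_a - p_b
  m <- mean(d)
  s <- stats::sd(d)
  if (is.na(s)) s <- 0
  list(mean_diff = m, loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s)
}

#' Serialize a study report as JSON
#'
#' @param report a `study_report`.
#' @param path output file.
#' @export
write_study_report <- function(report, path) {
  keep <- report
  keep$models <- lapply(keep$models, strip_unserializable)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE, na = "null")
  invisible(path)
}

strip_unserializable <- function(x) {
  if (is.list(x)) x[!vapply(x, is.function, TRUE)] else x
}

#' Structural validation of a study report
#'
#' Checks the report against the schema shipped in
#' `inst/schema/study_report_schema.json`: required top-level sections and,
#' for every non-failed model entry, the required calibration fields.
#'
#' @param report a `study_report` (or a list parsed back from JSON).
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  required <- c("header", "models", "information_criteria", "icc",
                "standardized", "cv_shrinkage", "dev_val", "endogeneity")
  missing <- setdiff(required, names(report))
  if (length(missing))
    stop_named("report is missing section(s): %s", paste(missing, collapse = ", "))
  for (nm in names(report$models)) {
    r <- report$models[[nm]]
    if (!is.null(r$failed)) next
    need <- if (grepl("raw", nm)) "auc" else c("auc", "aic", "bic")
    miss <- setdiff(need, names(r))
    if (length(miss))
      stop_named("model '%s' report lacks field(s): %s", nm,
                 paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
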