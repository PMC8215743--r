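## Synthetic ICU registry cohorts with known endogeneity structure.
##
## The generator emulates a national adult intensive-care registry: patients
## nested in ICU sites, a severity score and diagnostic case-mix, mechanical
## ventilation as a non-randomised treatment, hospital length of stay (HLOS)
## and an algorithm-derived risk-of-death probability (ROD). Ventilation,
## log-HLOS and mortality share a trivariate normal latent-error structure so
## that both covariate endogeneity and endogenous treatment assignment are
## present by construction, with full ground truth retained for recovery
## tests.

REGISTRY_COLUMNS <- c("site_id", "hospital_level", "volume_decile", "age",
                      "severity", "dx_category", "ventilated", "hlos",
                      "rod", "died")

HOSPITAL_LEVELS <- c("metropolitan", "private", "rural_regional", "tertiary")
## share of ICUs by classification in the emulated registry year
HOSPITAL_LEVEL_PROBS <- c(0.17, 0.325, 0.065, 0.44)
N_DX <- 28L

#' Configuration for the synthetic registry generator
#'
#' Defaults encode the cohort the package emulates: 124 ICUs, hospital
#' mortality 8.82%, 43.7% ventilated, age 61.8 (SD 17.5) years, severity
#' score 54.5 (SD 25.6), and latent error correlations
#' (ventilation-mortality, logHLOS-mortality, ventilation-logHLOS) of
#' (-0.248, -0.315, 0.119). Continuous coefficients are per decade of age and
#' per population SD of severity; the first level of each categorical is the
#' reference.
#'
#' @param n_patients number of patients.
#' @param n_sites number of ICU sites (>= 2).
#' @param site_sd SD of the site random intercept in the mortality equation
#'   (latent probit scale).
#' @param site_severity_sd SD of the site-level shift in mean severity
#'   (case-mix heterogeneity across sites, in score points).
#' @param corr_vm,corr_hm,corr_vh latent error correlations:
#'   ventilation-mortality, logHLOS-mortality, ventilation-logHLOS.
#' @param sigma_h SD of the log-HLOS error.
#' @param beta_outcome named list of mortality-equation coefficients:
#'   `intercept` (NA = calibrate to `target_mortality`), `age`, `severity`,
#'   `ventilated` (structural treatment effect), `log_hlos`.
#' @param gamma_treatment named list of ventilation-equation coefficients:
#'   `intercept` (NA = calibrate), `age`, `severity`, and instrument effect
#'   vectors `dx_category` (length 28), `hospital_level` (4),
#'   `volume_decile` (10).
#' @param delta_hlos named list of log-HLOS-equation coefficients: as
#'   `gamma_treatment` plus `ventilated` (treatment effect on log stay).
#' @param rod_noise_sd SD of the link-scale noise added to the true linear
#'   predictor when generating the ROD probability.
#' @param target_mortality,target_ventilated marginal proportions the
#'   calibrated intercepts must reproduce.
#' @param seed master seed; covariates, errors, site effects and ROD noise
#'   use independent substreams derived from it.
#' @return object of class `registry_config`.
#' @export
registry_config <- function(n_patients = 20000L,
                            n_sites = 124L,
                            site_sd = 0.13,
                            site_severity_sd = 10,
                            corr_vm = -0.248,
                            corr_hm = -0.315,
                            corr_vh = 0.119,
                            sigma_h = 0.8,
                            beta_outcome = list(
                              intercept = NA_real_, age = 0.25,
                              severity = 1.0, ventilated = 0.25,
                              log_hlos = 0.15),
                            gamma_treatment = list(
                              intercept = NA_real_, age = 0.2,
                              severity = 0.45,
                              dx_category = seq(-0.4, 0.4, length.out = N_DX),
                              hospital_level = c(0, 0.15, -0.1, 0.25),
                              volume_decile = seq(0, 0.25, length.out = 10)),
                            delta_hlos = list(
                              intercept = 2.1, age = 0.05, severity = 0.25,
                              dx_category = 0.8 * rev(seq(-0.4, 0.4, length.out = N_DX)),
                              hospital_level = c(0, -0.1, 0.2, 0.1),
                              volume_decile = seq(0, -0.2, length.out = 10),
                              ventilated = 0.3),
                            rod_noise_sd = 0.5,
                            target_mortality = 0.0882,
                            target_ventilated = 0.437,
                            seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), n_sites = as.integer(n_sites),
              site_sd = site_sd, site_severity_sd = site_severity_sd,
              corr_vm = corr_vm, corr_hm = corr_hm, corr_vh = corr_vh,
              sigma_h = sigma_h, beta_outcome = beta_outcome,
              gamma_treatment = gamma_treatment, delta_hlos = delta_hlos,
              rod_noise_sd = rod_noise_sd,
              target_mortality = target_mortality,
              target_ventilated = target_ventilated, seed = as.integer(seed))
  class(cfg) <- "registry_config"
  validate_registry_config(cfg)
  cfg
}

#' Validate a registry configuration
#'
#' Checks the structural constraints a generator configuration must satisfy:
#' enough sites and patients, nonnegative variance components, targets
#' strictly inside (0, 1), a positive-definite latent error correlation
#' matrix and instrument coefficient vectors of the right lengths.
#'
#' @param cfg a [registry_config()].
#' @return the configuration, invisibly, when valid.
#' @export
validate_registry_config <- function(cfg) {
  if (cfg$n_sites < 2) stop_named("n_sites must be >= 2")
  if (cfg$n_patients < cfg$n_sites)
    stop_named("n_patients must be at least n_sites so every site is populated")
  if (cfg$site_sd < 0) stop_named("site_sd must be nonnegative")
  if (cfg$sigma_h <= 0) stop_named("sigma_h must be positive")
  for (p in c("target_mortality", "target_ventilated"))
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1)
      stop_named("%s must lie strictly inside (0, 1)", p)
  R <- latent_corr_matrix(cfg)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop_named("latent error correlation matrix (corr_vm, corr_hm, corr_vh) is not positive definite")
  stopifnot(length(cfg$gamma_treatment$dx_category) == N_DX,
            length(cfg$gamma_treatment$hospital_level) == 4L,
            length(cfg$gamma_treatment$volume_decile) == 10L,
            length(cfg$delta_hlos$dx_category) == N_DX)
  invisible(cfg)
}

## order of margins: (ventilation, log-HLOS, mortality)
latent_corr_matrix <- function(cfg) {
  matrix(c(1, cfg$corr_vh, cfg$corr_vm,
           cfg$corr_vh, 1, cfg$corr_hm,
           cfg$corr_vm, cfg$corr_hm, 1), 3, 3,
         dimnames = rep(list(c("ventilation", "log_hlos", "mortality")), 2))
}

## Bisection on an equation intercept so the realised binary marginal hits
## the target. eta is the linear predictor excluding the intercept.
calibrate_intercept <- function(eta, target, equation, max_iter = 100L) {
  f <- function(b0) mean(eta + b0 > 0) - target
  lo <- -20; hi <- 20
  if (f(lo) > 0 || f(hi) < 0)
    stop_named("intercept calibration failed to bracket the %s equation target", equation)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f(mid)) <= 0.5 / length(eta) || (hi - lo) < 1e-12)
      return(mid)
  }
  stop_named("intercept calibration did not converge in %d iterations for the %s equation",
             max_iter, equation)
}

## centred covariate transforms used by all generator equations
age_std <- function(age) (age - 61.8) / 10
severity_std <- function(severity) (severity - 54.5) / 25.6

#' Generate a synthetic ICU registry cohort
#'
#' Draws site attributes and random intercepts, patient covariates, and a
#' trivariate normal latent error vector per patient; ventilation is assigned
#' by a probit first stage, log-HLOS by a linear first stage that includes
#' the ventilation effect, and hospital mortality by a probit outcome
#' equation containing the structural ventilation and log-HLOS effects plus
#' the site intercept. Intercepts of the two probit equations are calibrated
#' by bisection so the realised marginals match the configured targets. The
#' ROD probability is a noisy monotone (probit-link) transform of the true
#' mortality linear predictor and is therefore endogenous by construction.
#'
#' @param config a [registry_config()].
#' @return list of class `registry` with elements `table` (the patient-level
#'   data.frame), `truth` (ground-truth parameters, including calibrated
#'   intercepts, site intercepts and the latent correlation matrix) and
#'   `latent` (the realised latent error draws, site random intercepts per
#'   patient and linear predictors, for recovery diagnostics).
#' @export
generate_registry <- function(config) {
  validate_registry_config(config)
  n <- config$n_patients
  J <- config$n_sites

  ## --- sites: classification, volume, random intercept, case-mix shift ---
  site <- with_substream(config$seed, 1L, {
    list(hospital_level = sample(HOSPITAL_LEVELS, J, replace = TRUE,
                                 prob = HOSPITAL_LEVEL_PROBS),
         volume_decile = sample(1:10, J, replace = TRUE),
         u = stats::rnorm(J, 0, config$site_sd),
         severity_shift = stats::rnorm(J, 0, config$site_severity_sd))
  })

  ## --- patient covariates ---
  cov <- with_substream(config$seed, 2L, {
    w <- site$volume_decile
    idx <- sample.int(J, n, replace = TRUE, prob = w / sum(w))
    idx[seq_len(J)] <- seq_len(J)  # every site populated
    lo <- stats::pnorm(16, 61.8, 17.5); hi <- stats::pnorm(100, 61.8, 17.5)
    age <- stats::qnorm(stats::runif(n, lo, hi), 61.8, 17.5)
    shape <- (54.5 / 25.6)^2
    rate <- shape / 54.5
    sev_raw <- stats::rgamma(n, shape = shape, rate = rate) +
      site$severity_shift[idx]
    severity <- as.integer(pmin(299, pmax(0, round(sev_raw))))
    dx <- sample.int(N_DX, n, replace = TRUE,
                     prob = (1 / seq_len(N_DX)) / sum(1 / seq_len(N_DX)))
    list(site = idx, age = age, severity = severity, dx = dx)
  })

  ## --- correlated latent errors (ventilation, log-HLOS, mortality) ---
  R <- latent_corr_matrix(config)
  D <- diag(c(1, config$sigma_h, 1))
  eps <- with_substream(config$seed, 3L,
                        MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = D %*% R %*% D))
  colnames(eps) <- c("eps_v", "eps_h", "eps_m")

  a <- age_std(cov$age)
  s <- severity_std(cov$severity)
  hl_idx <- match(site$hospital_level[cov$site], HOSPITAL_LEVELS)
  vd_idx <- site$volume_decile[cov$site]

  ## --- ventilation assignment (probit first stage) ---
  g <- config$gamma_treatment
  eta_v <- g$age * a + g$severity * s + g$dx_category[cov$dx] +
    g$hospital_level[hl_idx] + g$volume_decile[vd_idx] + eps[, "eps_v"]
  gamma0 <- if (is.na(g$intercept))
    calibrate_intercept(eta_v, config$target_ventilated, "treatment")
  else g$intercept
  ventilated <- as.integer(gamma0 + eta_v > 0)

  ## --- log hospital length of stay ---
  d <- config$delta_hlos
  h <- d$intercept + d$age * a + d$severity * s + d$dx_category[cov$dx] +
    d$hospital_level[hl_idx] + d$volume_decile[vd_idx] +
    d$ventilated * ventilated + eps[, "eps_h"]
  hlos <- exp(h)

  ## --- hospital mortality ---
  b <- config$beta_outcome
  u_i <- site$u[cov$site]
  eta_m <- b$age * a + b$severity * s + b$ventilated * ventilated +
    b$log_hlos * h + u_i + eps[, "eps_m"]
  beta0 <- if (is.na(b$intercept))
    calibrate_intercept(eta_m, config$target_mortality, "outcome")
  else b$intercept
  died <- as.integer(beta0 + eta_m > 0)

  ## --- ROD: noisy monotone transform of the true linear predictor ---
  lp_true <- beta0 + eta_m - eps[, "eps_m"]
  rod <- with_substream(config$seed, 4L, {
    p <- stats::pnorm(lp_true + stats::rnorm(n, 0, config$rod_noise_sd))
    pmin(pmax(p, 1e-6), 1 - 1e-6)
  })

  table <- data.frame(
    site_id = sprintf("s%03d", cov$site),
    hospital_level = site$hospital_level[cov$site],
    volume_decile = sprintf("d%02d", vd_idx),
    age = cov$age,
    severity = cov$severity,
    dx_category = sprintf("dx%02d", cov$dx),
    ventilated = ventilated,
    hlos = hlos,
    rod = rod,
    died = died,
    stringsAsFactors = FALSE)

  truth <- list(
    config = unclass(config),
    intercepts = c(treatment = gamma0, outcome = beta0),
    site_intercepts = site$u,
    site_severity_shift = site$severity_shift,
    site_hospital_level = site$hospital_level,
    site_volume_decile = site$volume_decile,
    latent_correlation = R)

  latent <- data.frame(site = cov$site, eps, u = u_i,
                       lp_outcome = beta0 + eta_m - eps[, "eps_m"])

  structure(list(table = table, truth = truth, latent = latent),
            class = "registry")
}

#' Simulate counterfactual mortality under forced treatment assignment
#'
#' Redraws the (log-HLOS, mortality) latent errors from the ground-truth
#' distribution, forces ventilation to `treat` for every patient, propagates
#' the forced treatment through the length-of-stay equation and returns the
#' simulated mortality indicator. Averaging over draws gives the generator's
#' true potential-outcome mean, independent of any fitted model.
#'
#' @param truth `truth` element of a [generate_registry()] result.
#' @param table the matching registry table.
#' @param treat 0 or 1, the forced ventilation status.
#' @param seed RNG seed for the fresh error draws.
#' @return integer vector of simulated mortality indicators.
#' @export
simulate_counterfactual <- function(truth, table, treat, seed = 1L) {
  cfg <- truth$config
  n <- nrow(table)
  R <- truth$latent_correlation[2:3, 2:3]
  D <- diag(c(cfg$sigma_h, 1))
  set.seed(seed)
  eps <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = D %*% R %*% D)
  a <- age_std(table$age)
  s <- severity_std(table$severity)
  dx <- as.integer(sub("dx", "", table$dx_category))
  hl <- match(table$hospital_level, HOSPITAL_LEVELS)
  vd <- as.integer(sub("d", "", table$volume_decile))
  site <- as.integer(sub("s", "", table$site_id))
  d <- cfg$delta_hlos
  h <- d$intercept + d$age * a + d$severity * s + d$dx_category[dx] +
    d$hospital_level[hl] + d$volume_decile[vd] + d$ventilated * treat + eps[, 1]
  b <- cfg$beta_outcome
  eta <- truth$intercepts["outcome"] + b$age * a + b$severity * s +
    b$ventilated * treat + b$log_hlos * h +
    truth$site_intercepts[site] + eps[, 2]
  as.integer(eta > 0)
}

#' Write / read a registry table as CSV
#'
#' The CSV round-trip is lossless: categorical columns are stored as labels,
#' binaries as 0/1, and doubles with shortest-exact-round-trip precision.
#'
#' @param table a registry table.
#' @param path file path.
#' @return `write_registry` returns `path` invisibly; `read_registry` returns
#'   the table.
#' @export
write_registry <- function(table, path) {
  check_registry_columns(table)
  data.table::fwrite(table[, REGISTRY_COLUMNS], path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop_named("registry file not found: %s", path)
  dt <- data.table::fread(path, colClasses = list(
    character = c("site_id", "hospital_level", "volume_decile", "dx_category"),
    numeric = c("age", "hlos", "rod"),
    integer = c("severity", "ventilated", "died")), data.table = FALSE)
  check_registry_columns(dt)
  dt[, REGISTRY_COLUMNS]
}

check_registry_columns <- function(table) {
  missing <- setdiff(REGISTRY_COLUMNS, names(table))
  if (length(missing))
    stop_named("registry table is missing column(s): %s",
               paste(missing, collapse = ", "))
  invisible(table)
}

#' Serialize ground-truth parameters as JSON
#'
#' @param truth `truth` element of a [generate_registry()] result.
#' @param path file path.
#' @export
write_true_parameters <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
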