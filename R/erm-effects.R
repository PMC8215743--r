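## Potential-outcome treatment effects and marginal-effect grids for fitted
## extended probit models.

## Mean potential-outcome probability per patient under treatment forced to
## v, integrating over the latent errors consistently with the fitted model:
## the continuous endogenous variable is replaced by its structural equation
## under v, so the composite outcome error is
## lambda_H * eps_h + eps_m ~ N(0, 1 + lH^2 s^2 + 2 lH s rho_hm).
erm_pom <- function(theta, mats, spec, v) {
  id <- mats$idx
  beta <- theta[id$beta]
  xn <- colnames(mats$X)
  if (mats$has_t && mats$has_c) {
    jt <- match(spec$treatment, xn)
    jh <- match(spec$cont_endog, xn)
    lamV <- beta[jt]; lamH <- beta[jh]
    lp0 <- drop(mats$X[, -c(jt, jh), drop = FALSE] %*% beta[-c(jt, jh)])
    delta <- theta[id$delta]
    zn <- colnames(mats$Zh)
    kt <- match(spec$treatment, zn)
    if (!is.na(kt)) {
      mh <- drop(mats$Zh[, -kt, drop = FALSE] %*% delta[-kt]) + delta[kt] * v
    } else {
      mh <- drop(mats$Zh %*% delta)
    }
    sig <- exp(theta[id$lsig])
    rhm <- tanh(theta[id$ahm])
    s2 <- 1 + lamH^2 * sig^2 + 2 * lamH * sig * rhm
    stats::pnorm((lp0 + lamV * v + lamH * mh) / sqrt(max(s2, 1e-12)))
  } else if (mats$has_t) {
    jt <- match(spec$treatment, xn)
    lamV <- beta[jt]
    lp0 <- drop(mats$X[, -jt, drop = FALSE] %*% beta[-jt])
    stats::pnorm(lp0 + lamV * v)
  } else {
    stop_named("potential outcomes require an active treatment equation")
  }
}

#' Average treatment effects from an extended probit fit
#'
#' Potential-outcome mortality probabilities with ventilation forced to 1
#' and to 0 for every patient (the continuous endogenous variable evaluated
#' at its structural prediction under each arm, errors integrated out), the
#' average treatment effect (ATE) over all patients, and the average effect
#' on the treated (ATET). Confidence intervals use the delta method on the
#' full parameter vector with the sandwich covariance.
#'
#' @param fit an `erm_fit` with an active treatment equation.
#' @param table the data the fit used.
#' @param conf confidence level.
#' @return list with `ate`, `atet` (each estimate, se, ci), `pom0`, `pom1`.
#' @export
treatment_effects <- function(fit, table, conf = 0.95) {
  spec <- fit$spec
  if (!spec$components %in% c("both", "treatment"))
    stop_named("treatment effects require an active treatment equation")
  mats <- erm_matrices(table, spec)
  if (!any(mats$V == 1)) stop_named("no treated patients: ATET undefined")
  th <- fit$theta
  treated <- mats$V == 1

  eff <- function(theta) {
    p1 <- erm_pom(theta, mats, spec, 1)
    p0 <- erm_pom(theta, mats, spec, 0)
    c(ate = mean(p1 - p0), atet = mean(p1[treated] - p0[treated]),
      pom0 = mean(p0), pom1 = mean(p1))
  }
  est <- eff(th)
  ## delta method: jacobian of (ate, atet) by central differences
  p <- length(th)
  J <- matrix(0, 2, p)
  eps <- 1e-5
  for (j in seq_len(p)) {
    tp <- th; tp[j] <- tp[j] + eps
    tm <- th; tm[j] <- tm[j] - eps
    J[, j] <- (eff(tp)[1:2] - eff(tm)[1:2]) / (2 * eps)
  }
  V <- J %*% fit$vcov %*% t(J)
  se <- sqrt(pmax(diag(V), 0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(ate = list(estimate = est[["ate"]], se = se[1],
                  ci = est[["ate"]] + c(-1, 1) * z * se[1]),
       atet = list(estimate = est[["atet"]], se = se[2],
                   ci = est[["atet"]] + c(-1, 1) * z * se[2]),
       pom0 = est[["pom0"]], pom1 = est[["pom1"]])
}

#' Marginal-effect grid under counterfactual treatment scenarios
#'
#' For each grid value, sets the grid variable to that value for every
#' patient, fixes treatment at 0 and at 1 (counterfactual scenarios),
#' averages the predicted mortality probability, and reports delta-method
#' confidence intervals (sandwich covariance, so covariate sampling and
#' misspecification are accounted for) together with the
#' ventilated-minus-unventilated contrast.
#'
#' @param fit an `erm_fit` with an active treatment equation.
#' @param table the data the fit used.
#' @param grid_var name of an outcome-equation covariate.
#' @param grid_values numeric grid.
#' @param conf confidence level.
#' @return data.frame with one row per grid value: predicted mortality and
#'   CI under each scenario, the contrast with its CI, and a flag for the
#'   contrast CI excluding 0.
#' @export
margins_grid <- function(fit, table, grid_var, grid_values, conf = 0.95) {
  spec <- fit$spec
  if (!spec$components %in% c("both", "treatment"))
    stop_named("margins_grid requires an active treatment equation")
  if (!grid_var %in% names(table))
    stop_named("grid variable '%s' not found", grid_var)
  if (!grid_var %in% spec$outcome_terms)
    stop_named("grid variable '%s' is not an outcome-equation covariate", grid_var)
  rng <- range(table[[grid_var]])
  if (any(grid_values < rng[1] | grid_values > rng[2]))
    warning("grid value(s) outside the observed support of ", grid_var)

  th <- fit$theta
  p <- length(th)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- vector("list", length(grid_values))
  for (i in seq_along(grid_values)) {
    tab2 <- table
    tab2[[grid_var]] <- grid_values[i]
    mats2 <- erm_matrices(tab2, spec)
    mfun <- function(theta) c(mean(erm_pom(theta, mats2, spec, 0)),
                              mean(erm_pom(theta, mats2, spec, 1)))
    est <- mfun(th)
    J <- matrix(0, 2, p)
    eps <- 1e-5
    for (j in seq_len(p)) {
      tp <- th; tp[j] <- tp[j] + eps
      tm <- th; tm[j] <- tm[j] - eps
      J[, j] <- (mfun(tp) - mfun(tm)) / (2 * eps)
    }
    V <- J %*% fit$vcov %*% t(J)
    se <- sqrt(pmax(diag(V), 0))
    dse <- sqrt(max(V[1, 1] + V[2, 2] - 2 * V[1, 2], 0))
    contrast <- est[2] - est[1]
    rows[[i]] <- data.frame(
      grid_value = grid_values[i],
      p_unventilated = est[1],
      p_unventilated_lo = est[1] - z * se[1], p_unventilated_hi = est[1] + z * se[1],
      p_ventilated = est[2],
      p_ventilated_lo = est[2] - z * se[2], p_ventilated_hi = est[2] + z * se[2],
      contrast = contrast,
      contrast_lo = contrast - z * dse, contrast_hi = contrast + z * dse,
      contrast_excludes_0 = (contrast - z * dse) > 0 | (contrast + z * dse) < 0)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test a continuous covariate for endogeneity
#'
#' Fits the extended probit with `variable` as the single endogenous
#' continuous regressor (instruments in its first stage) and returns its
#' error correlation with the outcome together with the Wald test of
#' exogeneity (rho = 0).
#'
#' @param table data.
#' @param variable expression (string) for the suspect covariate, e.g.
#'   `"severity"` or `"log(rod)"`.
#' @param instruments first-stage terms (must include at least one term
#'   excluded from the outcome equation).
#' @param outcome binary outcome column.
#' @param outcome_terms exogenous outcome-equation terms.
#' @return list with `rho`, `ci`, `p_value`, the full `rho_table` row and
#'   the underlying `erm_fit`.
#' @export
exogeneity_check <- function(table, variable, instruments,
                             outcome = "died",
                             outcome_terms = c("age", "severity")) {
  vars_used <- all.vars(parse(text = variable))
  missing_vars <- setdiff(vars_used, names(table))
  if (length(missing_vars))
    stop_named("variable '%s' not found in the table", missing_vars[1])
  outcome_terms <- setdiff(outcome_terms, variable)
  sp <- erm_spec(outcome = outcome, outcome_terms = outcome_terms,
                 cont_endog = variable, cont_terms = instruments,
                 components = "continuous")
  fit <- fit_erm(table, sp)
  row <- fit$rho_table[fit$rho_table$correlation == "continuous_vs_outcome", ]
  list(rho = row$estimate, ci = c(row$ci_lower, row$ci_upper),
       p_value = row$p_value, rho_table = row, fit = fit)
}
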