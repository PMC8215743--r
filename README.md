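# icuendo

Hospital-mortality modelling with endogenous covariates and endogenous
treatment assignment, built around a synthetic ICU registry with known
ground truth.

Registry-based mortality models routinely include covariates that are
determined *together with* the outcome rather than before it: mechanical
ventilation is assigned partly on unmeasured acuity, length of stay is cut
short by death, and externally estimated risk-of-death scores are functions
of the outcome's own predictors. When such a variable's error term is
correlated with the mortality equation's error term, single-equation
estimators (logistic, probit, linear probability) are biased and
inconsistent no matter how large the registry. This package implements the
full modelling study around that problem:

- **Synthetic registry generator** — hierarchical cohorts (patients nested
  in ICU sites) with a trivariate correlated latent-error structure linking
  ventilation, log hospital length of stay (HLOS) and mortality, instruments
  at the diagnosis and site level, and complete ground truth for recovery
  tests. Default marginals: ~8.8% hospital mortality, ~43.7% ventilated,
  124 sites.
- **Single-level binary models** — logit, probit and the linear probability
  model (LPM), each with optional provider fixed effects; the discriminant
  transform of LPM coefficients to the logistic scale (multiplier
  `K = N/RSS`); unit-interval restriction; full X-Y coefficient
  standardisation and cross-model comparison.
- **Random-intercept models** — logit and probit via adaptive Gauss-Hermite
  quadrature, intraclass correlations (residual constants `pi^2/3` and 1)
  and the dichotomous latent R-squared.
- **Calibration suite** — ROC AUC, Hosmer-Lemeshow, the calibration belt
  (polynomial recalibration with forward LR degree selection), binned
  residuals, CITL / calibration slope / E:O, repeated k-fold shrinkage and
  development/validation reports.
- **Extended probit (the core estimator)** — one-step maximum likelihood for
  a probit outcome jointly with a probit treatment-assignment equation and a
  linear equation for a continuous endogenous regressor, trivariate-normal
  errors with freely estimated correlations, sandwich inference on the
  Fisher-z scale, average treatment effects (ATE/ATET) from potential-outcome
  means, marginal-effect grids under counterfactual ventilation scenarios,
  and exogeneity checks for suspect covariates.

## Worked example

```r
library(icuendo)

## a cohort whose ventilation and length-of-stay errors are correlated with
## the mortality error (the generator defaults)
reg <- generate_registry(registry_config(n_patients = 20000, seed = 1))
tab <- reg$table

## naive single-equation probit: the ventilation coefficient is biased
naive <- fit_binary(tab, model_spec("probit",
  covariates = c("age", "severity", "ventilated", "log(hlos)")))
naive$coefficients["ventilated"]

## joint estimation with instruments in the first stages recovers the
## structural effect and the error correlations
spec <- erm_spec(outcome = "died", outcome_terms = c("age", "severity"),
                 treatment = "ventilated", cont_endog = "log(hlos)",
                 components = "both")
fit <- fit_erm(tab, spec)
fit$rho_table                 # error correlations with robust CIs
treatment_effects(fit, tab)   # ATE / ATET with delta-method CIs
margins_grid(fit, tab, "severity", c(40, 80, 120))

## is the severity score itself endogenous? (it is not, by construction)
exogeneity_check(tab, "severity",
                 instruments = c("age", "dx_category", "hospital_level",
                                 "volume_decile"),
                 outcome_terms = c("age", "ventilated"))$p_value
```

## Installing and testing

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "icuendo", load_package = "installed")'
```

The test suite contains property-based acceptance tests: correlation and
variance-component recovery from the generator ground truth, a Monte-Carlo
oracle for the joint likelihood, null-calibration checks of the diagnostic
machinery, and the naive-vs-joint bias contrast that motivates the
estimator.

Imports: `MASS`, `lme4`, `sandwich`, `data.table`, `jsonlite`. The
bivariate-normal CDF at the heart of the joint likelihood is implemented
in-package (Gauss-Legendre/tail-expansion hybrid, ~1e-15 accuracy).
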