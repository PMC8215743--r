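Package: icuendo
Title: Endogeneity-Aware Hospital Mortality Modelling for ICU Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling hospital mortality in intensive-care registry
    cohorts when routinely recorded covariates (length of stay, an independent
    risk-of-death score) and treatment assignment (mechanical ventilation) are
    endogenous. Provides a synthetic registry generator with hierarchical
    provider effects and a trivariate correlated latent-error structure;
    logit, probit and linear-probability fits with provider fixed effects and
    the Haggstrom linear-discriminant transform; random-intercept logit and
    probit with adaptive Gauss-Hermite quadrature, intraclass correlation and
    the McKelvey-Zavoina dichotomous R-squared; a calibration suite (ROC AUC,
    Hosmer-Lemeshow, calibration belt, binned residuals, weak-calibration
    indices, cross-validated shrinkage); and a maximum-likelihood extended
    probit with an endogenous continuous regressor and an endogenous binary
    treatment, including error-correlation inference, average treatment
    effects and marginal-effect grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    sandwich,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
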