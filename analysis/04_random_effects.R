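#!/usr/bin/env Rscript

## Stage 4 — random-intercept (provider) models.
##
## Logit and probit with patients nested in ICU sites, estimated by adaptive
## Gauss-Hermite quadrature; unconditional and conditional intraclass
## correlations and the dichotomous (latent) R-squared.

suppressPackageStartupMessages(library(icuendo))

tab <- read_registry("results/registry.csv")
covs <- c("age", "severity", "ventilated")

rows <- lapply(c("logit", "probit"), function(link) {
  null <- fit_re(tab, link, character(0))
  full <- fit_re(tab, link, covs)
  data.frame(link = link,
             tau2_null = null$tau2, tau2_full = full$tau2,
             icc_unconditional = icc(null$tau2, link),
             icc_conditional = icc(full$tau2, link),
             r2_dichot = r2_dichot(full, tab),
             loglik = full$loglik, aic = full$aic, bic = full$bic,
             boundary = full$boundary)
})
re <- do.call(rbind, rows)
data.table::fwrite(re, "results/random_effects.csv")
print(re, row.names = FALSE)
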