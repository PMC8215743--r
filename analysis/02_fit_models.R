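#!/usr/bin/env Rscript

## Stage 2 — fit the single-level mortality models.
##
## Logit, probit and linear probability models, each vanilla and with
## provider fixed effects; the discriminant (K = N/RSS) transform of the two
## LPMs; the unit-interval-restricted LPM refit; and the standardised
## coefficient comparison of logit against probit and LPM.

suppressPackageStartupMessages(library(icuendo))

tab <- read_registry("results/registry.csv")

specs <- list(
  logit1 = model_spec("logit"),
  logit2 = model_spec("logit", site_fixed_effects = TRUE),
  probit1 = model_spec("probit"),
  probit2 = model_spec("probit", site_fixed_effects = TRUE),
  lpm1 = model_spec("linear", robust_se = TRUE),
  lpm2 = model_spec("linear", site_fixed_effects = TRUE, robust_se = TRUE))

fits <- lapply(specs, function(s) fit_binary(tab, s))
fits$lpm1_ldm <- lpm_to_logit(fits$lpm1, tab)
fits$lpm2_ldm <- lpm_to_logit(fits$lpm2, tab)

restr <- restrict_unit_interval(fits$lpm1, tab)
cat(sprintf("LPM predictions outside [0,1]: %d below 0 (%.1f%%), %d above 1 (%.1f%%)\n",
            restr$n_below0, 100 * restr$frac_below0,
            restr$n_above1, 100 * restr$frac_above1))
fits$lpm0 <- fit_binary(restr$table, specs$lpm1)

ic <- data.frame(model = names(fits),
                 loglik = sapply(fits, `[[`, "loglik"),
                 aic = sapply(fits, `[[`, "aic"),
                 bic = sapply(fits, `[[`, "bic"),
                 n_used = sapply(fits, `[[`, "n_used"))
data.table::fwrite(ic, "results/base_model_fit.csv")
print(ic, row.names = FALSE)

## standardised coefficients: logit as the comparator
std <- list(logit = standardize_xy(fits$logit1),
            probit = standardize_xy(fits$probit1),
            lpm_all_n = standardize_xy(fits$lpm1),
            lpm_01 = standardize_xy(fits$lpm0))
cmp <- do.call(rbind, lapply(c("probit", "lpm_all_n", "lpm_01"), function(m) {
  cs <- compare_standardized(std$logit, std[[m]])
  data.frame(versus = m, slope = cs$slope, se = cs$se,
             ci_lower = cs$ci[1], ci_upper = cs$ci[2], p_value = cs$p_value)
}))
data.table::fwrite(cmp, "results/standardized_comparison.csv")
print(cmp, row.names = FALSE)

## limits of agreement between logit and transformed-LPM probabilities
loa <- loa_summary(fits$logit1$fitted, fits$lpm1_ldm$fitted)
cat(sprintf("logit vs transformed-LPM probabilities: mean diff %.4f, LOA [%.4f, %.4f]\n",
            loa$mean_diff, loa$loa_lower, loa$loa_upper))
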