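#!/usr/bin/env Rscript

## Stage 1 — simulate the synthetic ICU registry.
##
## Generates a cohort with the study's default endogeneity structure
## (correlated latent errors linking ventilation, log length-of-stay and
## mortality; site random intercepts; instruments at the site and diagnosis
## level) and writes the patient table plus the generator ground truth.

suppressPackageStartupMessages(library(icuendo))

seed <- 20240101L
n_patients <- 50000L

dir.create("results", showWarnings = FALSE)

cfg <- registry_config(n_patients = n_patients, seed = seed)
reg <- generate_registry(cfg)

write_registry(reg$table, "results/registry.csv")
write_true_parameters(reg$truth, "results/true_parameters.json")

cat(sprintf("cohort: %d patients, %d sites\n", nrow(reg$table), cfg$n_sites))
cat(sprintf("hospital mortality: %.2f%%  ventilated: %.1f%%\n",
            100 * mean(reg$table$died), 100 * mean(reg$table$ventilated)))
cat(sprintf("latent error correlations (v-m, h-m, v-h): %.3f %.3f %.3f\n",
            cor(reg$latent$eps_v, reg$latent$eps_m),
            cor(reg$latent$eps_h, reg$latent$eps_m),
            cor(reg$latent$eps_v, reg$latent$eps_h)))
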