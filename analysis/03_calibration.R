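#!/usr/bin/env Rscript

## Stage 3 — discrimination and calibration of the single-level models.
##
## AUC, Hosmer-Lemeshow, calibration belt, binned residuals, CITL / slope /
## E:O, cross-validated shrinkage and the development/validation split
## report for the vanilla logit.

suppressPackageStartupMessages(library(icuendo))

tab <- read_registry("results/registry.csv")
y <- tab$died
seed <- 20240103L

specs <- list(
  logit1 = model_spec("logit"),
  logit2 = model_spec("logit", site_fixed_effects = TRUE),
  probit1 = model_spec("probit"),
  probit2 = model_spec("probit", site_fixed_effects = TRUE),
  logit1_loghlos = model_spec("logit", covariates = c(default_terms(), "log(hlos)")),
  logit1_logrod = model_spec("logit", covariates = c(default_terms(), "log(rod)")))

rows <- lapply(names(specs), function(nm) {
  f <- fit_binary(tab, specs[[nm]])
  r <- calibration_report(f, if (length(f$dropped_sites))
    tab$died[!(tab$site_id %in% f$dropped_sites)] else y)
  data.frame(model = nm, auc = r$auc, hl_stat = r$hl_stat, hl_p = r$hl_p,
             belt_degree = r$belt_degree, belt_p = r$belt_p, citl = r$citl,
             slope = r$slope, eo_ratio = r$eo_ratio,
             binned_coverage = r$binned_coverage, aic = r$aic, bic = r$bic)
})
perf <- do.call(rbind, rows)
data.table::fwrite(perf, "results/calibration_table.csv")
print(perf, row.names = FALSE)

cv <- cv_shrinkage(tab, specs$logit1, k = 10, reps = 2, seed = seed)
cat(sprintf("10-fold CV (2 reps): in-sample shrinkage %.2f%%, out-of-sample %.2f%%, overfit %.2f%%\n",
            cv$shrink_in, cv$shrink_out, cv$overfit_pct))

dv <- dev_val_report(tab, specs$logit1, seed = seed)
cat(sprintf("development: AUC %.3f CITL %.3f slope %.3f E:O %.3f\n",
            dv$development$auc, dv$development$citl, dv$development$slope,
            dv$development$eo_ratio))
cat(sprintf("validation:  AUC %.3f CITL %.3f slope %.3f E:O %.3f\n",
            dv$validation$auc, dv$validation$citl, dv$validation$slope,
            dv$validation$eo_ratio))
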