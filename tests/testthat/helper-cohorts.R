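## Shared, lazily built fixtures. Heavy objects are computed once per test
## run and reused across files / blocks.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, force(expr), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

## mid-sized default-parameter cohort for generic model tests
default_cohort <- function() cached("default8k", {
  generate_registry(registry_config(n_patients = 8000, n_sites = 30, seed = 101))
})

## small cohort for cheap structural tests
small_cohort <- function() cached("small3k", {
  generate_registry(registry_config(n_patients = 3000, n_sites = 12, seed = 202))
})

## one extended probit fit (both endogenous components) reused by effect,
## margins and print tests
cached_erm <- function() cached("erm8k", {
  tab <- default_cohort()$table
  sp <- erm_spec(outcome = "died", outcome_terms = c("age", "severity"),
                 treatment = "ventilated", cont_endog = "log(hlos)",
                 components = "both")
  list(fit = suppressWarnings(fit_erm(tab, sp)), table = tab, spec = sp)
})

## the 50-replicate extended-probit study shared by two acceptance blocks:
## correlation recovery and the naive-vs-structural bias contrast
erm_study <- function() cached("erm_study", {
  sp <- erm_spec(outcome = "died", outcome_terms = c("age", "severity"),
                 treatment = "ventilated", cont_endog = "log(hlos)",
                 components = "both")
  res <- lapply(1:50, function(s) {
    cfg <- registry_config(n_patients = 20000, seed = 1000 + s)
    tab <- generate_registry(cfg)$table
    f <- suppressWarnings(fit_erm(tab, sp))
    naive <- stats::glm(died ~ age + severity + ventilated + log(hlos),
                        data = tab, family = stats::binomial("probit"))
    c(rho = f$rho_table$estimate, se = f$rho_table$robust_se,
      lamV = f$coefficients$outcome[["ventilated"]],
      naive = stats::coef(naive)[["ventilated"]],
      conv = as.numeric(f$converged))
  })
  do.call(rbind, res)
})
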