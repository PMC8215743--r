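## Single-level binary outcome estimators: logit, probit and the linear
## probability model (LPM), each with optional provider (site) fixed effects,
## plus the Haggstrom linear-discriminant transform of LPM coefficients,
## unit-interval restriction of LPM predictions, and full X-Y coefficient
## standardisation.

#' Specify a binary outcome model
#'
#' @param link `"logit"`, `"probit"` or `"linear"` (OLS on the 0/1 outcome).
#' @param outcome name of the binary outcome column.
#' @param covariates character vector of model terms (formula syntax, e.g.
#'   `"age"`, `"log(hlos)"`, `"age:severity"`).
#' @param site_fixed_effects include ICU providers (`site_id`) as dummy-coded
#'   fixed effects.
#' @param robust_se report a heteroskedasticity-consistent (sandwich)
#'   covariance instead of the model-based one.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(link = c("logit", "probit", "linear"),
                       outcome = "died",
                       covariates = default_terms(),
                       site_fixed_effects = FALSE,
                       robust_se = FALSE) {
  link <- match.arg(link)
  structure(list(link = link, outcome = outcome, covariates = covariates,
                 site_fixed_effects = isTRUE(site_fixed_effects),
                 robust_se = isTRUE(robust_se)),
            class = "model_spec")
}

#' Default mortality-model term list
#'
#' Main effects of the registry covariates plus the age-by-severity and
#' severity-by-diagnosis interactions.
#' @return character vector of terms.
#' @export
default_terms <- function() {
  c("age", "severity", "dx_category", "hospital_level", "volume_decile",
    "ventilated", "age:severity", "severity:dx_category")
}

spec_formula <- function(spec) {
  rhs <- spec$covariates
  if (spec$site_fixed_effects) rhs <- c(rhs, "site_id")
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(spec$outcome, "~", paste(rhs, collapse = " + ")))
}

#' Fit a binary outcome model
#'
#' Maximum likelihood (IRLS) for logit/probit, ordinary least squares for the
#' linear probability model. With site fixed effects, sites whose outcomes
#' are all 0 or all 1 are perfectly predicted under logit/probit; their rows
#' are dropped and the site labels recorded (they are retained for the LPM).
#' Complete separation is reported as an explicit error rather than a silent
#' divergent coefficient.
#'
#' @param table a registry table (or any data.frame with the referenced
#'   columns).
#' @param spec a [model_spec()].
#' @return object of class `fit_result` with elements `coefficients`, `vcov`
#'   (sandwich if `robust_se`), `loglik`, `n_used`, `aic`, `bic`, `fitted`,
#'   `dropped_sites`, `link`, `spec` and the underlying `model` object.
#' @export
fit_binary <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  y <- table[[spec$outcome]]
  if (is.null(y)) stop_named("outcome column '%s' not found", spec$outcome)
  if (length(unique(y)) < 2)
    stop_named("outcome '%s' has a single class; cannot estimate", spec$outcome)

  dropped_sites <- character(0)
  dat <- table
  if (spec$site_fixed_effects && spec$link != "linear") {
    tab <- tapply(y, dat$site_id, function(v) mean(v))
    bad <- names(tab)[tab %in% c(0, 1)]
    if (length(bad)) {
      dropped_sites <- bad
      dat <- dat[!(dat$site_id %in% bad), , drop = FALSE]
    }
  }

  fml <- spec_formula(spec)
  if (spec$link == "linear") {
    fit <- stats::lm(fml, data = dat)
  } else {
    fit <- stats::glm(fml, data = dat,
                      family = stats::binomial(link = spec$link),
                      control = stats::glm.control(epsilon = 1e-10, maxit = 200))
    if (!fit$converged)
      stop_named("IRLS did not converge in 200 iterations (deviance %.6f)",
                 fit$deviance)
    check_separation(fit)
  }

  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n_used <- stats::nobs(fit)
  vc <- if (spec$robust_se) sandwich::vcovHC(fit, type = "HC1") else stats::vcov(fit)
  structure(list(
    coefficients = stats::coef(fit),
    vcov = vc,
    loglik = as.numeric(ll),
    n_used = n_used,
    aic = -2 * as.numeric(ll) + 2 * k,
    bic = -2 * as.numeric(ll) + k * log(n_used),
    fitted = as.numeric(stats::fitted(fit)),
    dropped_sites = dropped_sites,
    link = spec$link,
    spec = spec,
    model = fit), class = "fit_result")
}

#' Detect complete or quasi-complete separation in a binary fit
#'
#' Separation shows up as coefficients diverging on the standardised scale;
#' any coefficient exceeding 20 after scaling by its covariate SD raises an
#' error naming the offending term(s).
#'
#' @param fit a fitted `glm` (or the `model` element of a `fit_result`).
#' @return the fit, invisibly, when no separation is detected.
#' @export
check_separation <- function(fit) {
  b <- stats::coef(fit)
  X <- stats::model.matrix(fit)
  sdx <- apply(X, 2, stats::sd)
  scale <- ifelse(sdx > 0, sdx, 1)
  big <- which(abs(b * scale) > 20 & is.finite(b))
  if (length(big))
    stop_named("complete or quasi-complete separation detected (diverging coefficient(s): %s)",
               paste(names(b)[big], collapse = ", "))
  invisible(fit)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> link=%s n=%d loglik=%.2f aic=%.1f bic=%.1f\n",
              x$link, x$n_used, x$loglik, x$aic, x$bic))
  if (length(x$dropped_sites))
    cat("dropped perfectly-predicted sites:",
        paste(x$dropped_sites, collapse = ", "), "\n")
  invisible(x)
}

#' Haggstrom transform of an LPM fit to logistic-discriminant coefficients
#'
#' Multiplies the OLS slopes by `K = N / RSS` and maps the intercept by the
#' linear-discriminant rule `K * (b0 - p) + log(p / (1 - p))` with `p` the
#' outcome mean, then generates predicted probabilities through the logistic
#' link so they lie strictly inside (0, 1). At the OLS optimum with an
#' intercept the mean squared residual cannot exceed 1/4, so `K >= 4`.
#'
#' @param ols_fit a `fit_result` with `link == "linear"` and an intercept.
#' @param table the data the fit used.
#' @return a `fit_result` with logistic-link fitted probabilities.
#' @export
lpm_to_logit <- function(ols_fit, table) {
  if (ols_fit$link != "linear")
    stop_named("lpm_to_logit needs a linear (LPM) fit")
  b <- ols_fit$coefficients
  ## aliased (rank-deficient) columns carry NA coefficients and contribute
  ## nothing to the fit; drop them from the transform
  b <- b[!is.na(b)]
  if (!"(Intercept)" %in% names(b))
    stop_named("lpm_to_logit needs an intercept in the OLS fit")
  res <- stats::residuals(ols_fit$model)
  rss <- sum(res^2)
  if (rss <= 0) stop_named("degenerate LPM fit: zero residual sum of squares")
  n <- ols_fit$n_used
  K <- n / rss
  pbar <- mean(stats::model.frame(ols_fit$model)[[1L]])
  bt <- b * K
  bt["(Intercept)"] <- K * (b["(Intercept)"] - pbar) + qlogit(pbar)
  tt <- stats::terms(ols_fit$model)
  mf <- stats::model.frame(tt, data = table)
  X <- stats::model.matrix(tt, mf)
  keep <- intersect(colnames(X), names(bt))
  fitted <- as.numeric(stats::plogis(drop(X[, keep, drop = FALSE] %*% bt[keep])))
  out <- ols_fit
  out$coefficients <- bt
  out$fitted <- fitted
  out$link <- "logit"
  out$K <- K
  out$transformed <- TRUE
  ## likelihood of the transformed (not re-estimated) model under the
  ## logistic link, for information-criterion comparison
  y <- stats::model.response(mf)
  ll <- sum(stats::dbinom(y, 1, pmin(pmax(fitted, 1e-12), 1 - 1e-12), log = TRUE))
  k <- length(bt)
  out$loglik <- ll
  out$aic <- -2 * ll + 2 * k
  out$bic <- -2 * ll + k * log(length(y))
  out$vcov <- ols_fit$vcov * K^2
  out
}

#' Restrict LPM predictions to the unit interval
#'
#' @param fit a linear-link `fit_result`.
#' @param table the data the fit used.
#' @return list with the retained rows (`table`), counts `n_below0` /
#'   `n_above1`, the corresponding fractions, and the retained fitted values.
#' @export
restrict_unit_interval <- function(fit, table) {
  if (fit$link != "linear")
    stop_named("restrict_unit_interval applies to linear (LPM) fits")
  p <- fit$fitted
  below <- p < 0
  above <- p > 1
  keep <- !(below | above)
  out <- list(table = table[keep, , drop = FALSE],
              n_below0 = sum(below), n_above1 = sum(above),
              frac_below0 = mean(below), frac_above1 = mean(above),
              fitted = p[keep],
              empty = !any(keep))
  if (out$empty) warning("no predictions remain inside [0, 1]")
  out
}

#' Full X-Y standardisation of model coefficients
#'
#' Standardised coefficients are `b_k * sd(x_k) / sd(y*)`, where the latent
#' outcome variance is `var(x'b) + c` with residual constant `c = pi^2/3`
#' (logit), 1 (probit) or `RSS/N` (linear).
#'
#' @param fit a `fit_result`.
#' @param table the data the fit used (defaults to the stored model frame).
#' @return named vector of fully standardised coefficients (intercept
#'   excluded).
#' @export
standardize_xy <- function(fit, table = NULL) {
  X <- stats::model.matrix(fit$model)
  b <- fit$coefficients
  b <- b[!is.na(b)]
  X <- X[, names(b), drop = FALSE]
  lp <- drop(X %*% b)
  cres <- switch(fit$link,
                 logit = pi^2 / 3,
                 probit = 1,
                 linear = sum(stats::residuals(fit$model)^2) / fit$n_used)
  sd_y <- sqrt(stats::var(lp) + cres)
  keep <- setdiff(names(b), "(Intercept)")
  sdx <- apply(X[, keep, drop = FALSE], 2, stats::sd)
  zero <- names(sdx)[sdx == 0]
  if (length(zero))
    stop_named("zero-variance covariate(s): %s", paste(zero, collapse = ", "))
  b[keep] * sdx / sd_y
}

#' Regression comparison of two standardised coefficient vectors
#'
#' Regresses `beta_b` on `beta_a` (aligned by name when both are named) and
#' reports the slope with its 95% CI and p-value, mirroring the layout of
#' published standardised-coefficient comparisons.
#'
#' @param beta_a,beta_b standardised coefficient vectors of equal length
#'   (>= 3).
#' @param intercept include an intercept in the comparison regression
#'   (default) or force it through the origin.
#' @return list with `slope`, `se`, `p_value`, `ci` and the underlying `lm`.
#' @export
compare_standardized <- function(beta_a, beta_b, intercept = TRUE) {
  if (!is.null(names(beta_a)) && !is.null(names(beta_b))) {
    common <- intersect(names(beta_a), names(beta_b))
    beta_a <- beta_a[common]; beta_b <- beta_b[common]
  }
  if (length(beta_a) != length(beta_b))
    stop_named("coefficient vectors differ in length (%d vs %d)",
               length(beta_a), length(beta_b))
  if (length(beta_a) < 3) stop_named("need at least 3 aligned coefficients")
  fit <- if (intercept) stats::lm(beta_b ~ beta_a) else stats::lm(beta_b ~ beta_a - 1)
  sm <- summary(fit)$coefficients
  row <- "beta_a"
  ci <- stats::confint(fit)[row, ]
  list(slope = sm[row, "Estimate"], se = sm[row, "Std. Error"],
       p_value = sm[row, "Pr(>|t|)"], ci = unname(ci), model = fit)
}
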