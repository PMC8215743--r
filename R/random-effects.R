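## Random-intercept logit and probit models (patients nested in ICU sites),
## estimated by adaptive Gauss-Hermite quadrature through lme4, with the
## intraclass correlation and the McKelvey-Zavoina dichotomous R-squared.

#' Fit a random-intercept binary model
#'
#' Marginal maximum likelihood with adaptive Gauss-Hermite quadrature
#' (posterior mode and curvature re-centring per site, as implemented in
#' \pkg{lme4}). A near-zero variance estimate is reported with a boundary
#' flag rather than an error.
#'
#' @param table a registry table.
#' @param link `"logit"` or `"probit"`.
#' @param covariates character vector of fixed-effect terms.
#' @param outcome outcome column name.
#' @param site site (cluster) column name.
#' @param quadrature_points number of adaptive quadrature nodes (>= 5).
#' @param fix_tau_zero fit with the intercept variance constrained to zero
#'   (reduces to the single-level model).
#' @return object of class `re_fit`: `coefficients` (fixed effects), `tau2`,
#'   `loglik`, `aic`, `bic`, `posterior_modes` (per-site conditional modes),
#'   `quadrature_points`, `boundary`, `link` and the underlying `model`.
#' @export
fit_re <- function(table, link = c("logit", "probit"),
                   covariates = c("age", "severity", "ventilated"),
                   outcome = "died", site = "site_id",
                   quadrature_points = 12L, fix_tau_zero = FALSE) {
  link <- match.arg(link)
  if (quadrature_points < 5) stop_named("quadrature_points must be >= 5")
  y <- table[[outcome]]
  if (length(unique(y)) < 2) stop_named("outcome has a single class")
  if (length(unique(table[[site]])) < 2) stop_named("need >= 2 sites")

  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"

  if (fix_tau_zero) {
    ## tau^2 = 0 collapses the marginal likelihood to the single-level model
    fml <- stats::as.formula(paste(outcome, "~", rhs))
    g <- stats::glm(fml, data = table, family = stats::binomial(link = link),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 200))
    ll <- as.numeric(stats::logLik(g))
    k <- length(stats::coef(g))
    sites <- sort(unique(table[[site]]))
    return(structure(list(coefficients = stats::coef(g), tau2 = 0,
                          loglik = ll, aic = -2 * ll + 2 * k,
                          bic = -2 * ll + k * log(stats::nobs(g)),
                          posterior_modes = stats::setNames(rep(0, length(sites)), sites),
                          quadrature_points = as.integer(quadrature_points),
                          boundary = TRUE, link = link, model = g),
                     class = "re_fit"))
  }

  fml <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 |", site, ")"))
  ctrl <- lme4::glmerControl(optimizer = "nloptwrap", calc.derivs = FALSE)
  m <- lme4::glmer(fml, data = table, family = stats::binomial(link = link),
                   nAGQ = as.integer(quadrature_points), control = ctrl)
  tau2 <- as.numeric(lme4::VarCorr(m)[[site]])
  ll <- as.numeric(stats::logLik(m))
  k <- attr(stats::logLik(m), "df")
  pm <- lme4::ranef(m)[[site]][, 1]
  names(pm) <- rownames(lme4::ranef(m)[[site]])
  structure(list(coefficients = lme4::fixef(m), tau2 = tau2, loglik = ll,
                 aic = -2 * ll + 2 * k,
                 bic = -2 * ll + k * log(stats::nobs(m)),
                 posterior_modes = pm,
                 quadrature_points = as.integer(quadrature_points),
                 boundary = tau2 < 1e-6, link = link, model = m),
            class = "re_fit")
}

#' @export
print.re_fit <- function(x, ...) {
  cat(sprintf("<re_fit> link=%s tau2=%.4f loglik=%.2f (nAGQ=%d)%s\n",
              x$link, x$tau2, x$loglik, x$quadrature_points,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

## link-specific level-one latent residual variance
link_residual_var <- function(link) {
  switch(link, logit = pi^2 / 3, probit = 1,
         stop_named("unknown link '%s'", link))
}

#' Intraclass correlation for a clustered binary model
#'
#' `ICC = tau2 / (tau2 + c)` with `c = pi^2/3` for the logit link and 1 for
#' the probit link. Supply the null-model variance for the unconditional ICC
#' or the full-model variance for the conditional ICC.
#'
#' @param tau2 random-intercept variance (>= 0).
#' @param link `"logit"` or `"probit"`.
#' @return the intraclass correlation in \[0, 1).
#' @export
icc <- function(tau2, link = c("logit", "probit")) {
  link <- match.arg(link)
  if (any(tau2 < 0)) stop_named("tau2 must be nonnegative")
  tau2 / (tau2 + link_residual_var(link))
}

#' McKelvey-Zavoina dichotomous R-squared for a random-intercept model
#'
#' `R2 = sF2 / (sF2 + tau2 + sR2)` where `sF2` is the sample variance of the
#' fixed-part linear predictor and `sR2` the link residual constant.
#'
#' @param fit an `re_fit`.
#' @param table data on which to evaluate the fixed-part linear predictor
#'   (defaults to the fitting data).
#' @return explained latent variance in \[0, 1).
#' @export
r2_dichot <- function(fit, table = NULL) {
  stopifnot(inherits(fit, "re_fit"))
  if (fit$tau2 == 0 && inherits(fit$model, "glm")) {
    lp <- stats::predict(fit$model, newdata = table, type = "link")
  } else {
    lp <- stats::predict(fit$model, newdata = table, re.form = NA, type = "link")
  }
  sF2 <- stats::var(as.numeric(lp))
  sF2 / (sF2 + fit$tau2 + link_residual_var(fit$link))
}
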