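## Extended probit regression by one-step maximum likelihood: a probit
## outcome equation estimated jointly with a probit treatment-assignment
## equation and/or a linear equation for a continuous endogenous regressor,
## the three error terms jointly normal with freely estimated correlations.
## Instruments enter the auxiliary equations and are excluded from the
## outcome equation. Inference uses a sandwich (robust) covariance; error
## correlations are parameterised on the Fisher-z scale so estimates respect
## (-1, 1) by construction.

#' Specify an extended probit model
#'
#' @param outcome binary outcome column name.
#' @param outcome_terms exogenous terms of the outcome equation (the active
#'   endogenous variables are appended automatically and must not be listed).
#' @param treatment binary endogenous treatment column (used when
#'   `components` is `"both"` or `"treatment"`).
#' @param treatment_terms terms of the treatment (probit) equation.
#' @param cont_endog expression (as a string, e.g. `"log(hlos)"`) for the
#'   continuous endogenous regressor (used when `components` is `"both"` or
#'   `"continuous"`).
#' @param cont_terms terms of the continuous (linear) equation.
#' @param cont_includes_treatment include the treatment indicator in the
#'   continuous equation (default when both components are active).
#' @param components which endogenous components are active.
#' @return object of class `erm_spec`.
#' @export
erm_spec <- function(outcome = "died",
                     outcome_terms = c("age", "severity"),
                     treatment = "ventilated",
                     treatment_terms = c("age", "severity", "dx_category",
                                         "hospital_level", "volume_decile"),
                     cont_endog = "log(hlos)",
                     cont_terms = c("age", "severity", "dx_category",
                                    "hospital_level", "volume_decile"),
                     cont_includes_treatment = TRUE,
                     components = c("both", "treatment", "continuous")) {
  components <- match.arg(components)
  sp <- structure(list(outcome = outcome, outcome_terms = outcome_terms,
                       treatment = treatment, treatment_terms = treatment_terms,
                       cont_endog = cont_endog, cont_terms = cont_terms,
                       cont_includes_treatment = isTRUE(cont_includes_treatment),
                       components = components), class = "erm_spec")
  if (components %in% c("both", "treatment")) {
    if (treatment %in% outcome_terms)
      stop_named("the endogenous treatment must not appear in outcome_terms")
    if (!length(setdiff(treatment_terms, outcome_terms)))
      stop_named("treatment equation needs at least one excluded instrument")
  }
  if (components %in% c("both", "continuous")) {
    if (cont_endog %in% outcome_terms)
      stop_named("the endogenous continuous variable must not appear in outcome_terms")
    if (!length(setdiff(cont_terms, outcome_terms)))
      stop_named("continuous equation needs at least one excluded instrument")
  }
  sp
}

terms_matrix <- function(terms, table) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  stats::model.matrix(stats::as.formula(paste("~", rhs)), data = table)
}

## Assemble the design matrices, endogenous vectors and parameter index map.
erm_matrices <- function(table, spec) {
  M <- table[[spec$outcome]]
  if (is.null(M)) stop_named("outcome column '%s' not found", spec$outcome)
  has_t <- spec$components %in% c("both", "treatment")
  has_c <- spec$components %in% c("both", "continuous")
  V <- h <- NULL
  Zv <- Zh <- NULL
  if (has_t) {
    V <- table[[spec$treatment]]
    if (is.null(V)) stop_named("treatment column '%s' not found", spec$treatment)
    Zv <- terms_matrix(spec$treatment_terms, table)
  }
  if (has_c) {
    h <- tryCatch(eval(parse(text = spec$cont_endog), table, parent.frame()),
                  error = function(e)
                    stop_named("cannot evaluate endogenous variable '%s': %s",
                               spec$cont_endog, conditionMessage(e)))
    if (!is.numeric(h)) stop_named("endogenous variable '%s' is not numeric",
                                   spec$cont_endog)
    Zh <- terms_matrix(spec$cont_terms, table)
    if (has_t && spec$cont_includes_treatment) {
      Zh <- cbind(Zh, V)
      colnames(Zh)[ncol(Zh)] <- spec$treatment
    }
  }
  X <- terms_matrix(spec$outcome_terms, table)
  if (has_t) { X <- cbind(X, V); colnames(X)[ncol(X)] <- spec$treatment }
  if (has_c) { X <- cbind(X, h); colnames(X)[ncol(X)] <- spec$cont_endog }

  px <- ncol(X); pv <- if (has_t) ncol(Zv) else 0L; ph <- if (has_c) ncol(Zh) else 0L
  ## parameter layout: beta | gamma | delta | log sigma | atanh rho's
  idx <- list(beta = seq_len(px))
  pos <- px
  if (has_t) { idx$gamma <- pos + seq_len(pv); pos <- pos + pv }
  if (has_c) { idx$delta <- pos + seq_len(ph); pos <- pos + ph
               idx$lsig <- pos + 1L; pos <- pos + 1L }
  if (has_t) { idx$avm <- pos + 1L; pos <- pos + 1L }
  if (has_c) { idx$ahm <- pos + 1L; pos <- pos + 1L }
  if (has_t && has_c) { idx$avh <- pos + 1L; pos <- pos + 1L }
  list(X = X, Zv = Zv, Zh = Zh, M = M, V = V, h = h,
       has_t = has_t, has_c = has_c, idx = idx, n_par = pos,
       par_names = c(paste0("outcome:", colnames(X)),
                     if (has_t) paste0("treatment:", colnames(Zv)),
                     if (has_c) paste0("hlos:", colnames(Zh)),
                     if (has_c) "log_sigma",
                     if (has_t) "atanh_rho_vm",
                     if (has_c) "atanh_rho_hm",
                     if (has_t && has_c) "atanh_rho_vh"))
}

## Log-likelihood and (optionally) per-observation scores for all three
## component configurations. Scores were validated against central finite
## differences of the log-likelihood. `grad_only` skips materialising the
## n-by-p score matrix (the gradient is assembled from small crossproducts),
## which keeps the finite-difference information loop cheap.
erm_objective <- function(theta, mats, want_score = FALSE, grad_only = FALSE) {
  id <- mats$idx
  beta <- theta[id$beta]
  eta_m <- drop(mats$X %*% beta)
  qm <- 2 * mats$M - 1

  if (mats$has_t && mats$has_c) {
    gamma <- theta[id$gamma]; delta <- theta[id$delta]
    sig <- exp(theta[id$lsig])
    rvm <- tanh(theta[id$avm]); rhm <- tanh(theta[id$ahm]); rvh <- tanh(theta[id$avh])
    qv <- 2 * mats$V - 1
    eta_v <- drop(mats$Zv %*% gamma)
    e <- mats$h - drop(mats$Zh %*% delta)
    u <- e / sig
    cv <- sqrt(1 - rvh^2); cm <- sqrt(1 - rhm^2)
    kst <- rvm - rvh * rhm
    rstar <- kst / (cv * cm)
    if (abs(rstar) >= 1 - 1e-10)
      return(if (want_score) list(loglik = -Inf) else -Inf)
    wv <- qv * (eta_v + rvh * u) / cv
    wm <- qm * (eta_m + rhm * u) / cm
    r <- qv * qm * rstar
    P2 <- pbvnorm(wv, wm, r); P2[P2 < 1e-300] <- 1e-300
    ll <- sum(stats::dnorm(e, 0, sig, log = TRUE)) + sum(log(P2))
    if (!want_score && !grad_only) return(ll)
    om <- 1 - r * r
    g1 <- stats::dnorm(wv) * stats::pnorm((wm - r * wv) / sqrt(om)) / P2
    g2 <- stats::dnorm(wm) * stats::pnorm((wv - r * wm) / sqrt(om)) / P2
    gr <- dbvnorm(wv, wm, r) / P2
    dl_eta_m <- g2 * qm / cm
    dl_eta_v <- g1 * qv / cv
    dl_e <- -e / sig^2 + g1 * qv * rvh / (cv * sig) + g2 * qm * rhm / (cm * sig)
    dl_lsig <- (e^2 / sig^2 - 1) - g1 * qv * rvh * u / cv - g2 * qm * rhm * u / cm
    dwv_rvh <- qv * (u + (eta_v + rvh * u) * rvh / cv^2) / cv
    dwm_rhm <- qm * (u + (eta_m + rhm * u) * rhm / cm^2) / cm
    dr_rvm <- qv * qm / (cv * cm)
    dr_rvh <- qv * qm * (-rhm / (cv * cm) + kst * rvh / (cv^3 * cm))
    dr_rhm <- qv * qm * (-rvh / (cv * cm) + kst * rhm / (cv * cm^3))
    s_avm <- gr * dr_rvm * (1 - rvm^2)
    s_ahm <- (g2 * dwm_rhm + gr * dr_rhm) * (1 - rhm^2)
    s_avh <- (g1 * dwv_rvh + gr * dr_rvh) * (1 - rvh^2)
    if (grad_only) {
      g <- c(crossprod(mats$X, dl_eta_m), crossprod(mats$Zv, dl_eta_v),
             crossprod(mats$Zh, -dl_e), sum(dl_lsig), sum(s_avm),
             sum(s_ahm), sum(s_avh))
      return(list(loglik = ll, grad = g))
    }
    S <- cbind(mats$X * dl_eta_m, mats$Zv * dl_eta_v, mats$Zh * (-dl_e),
               dl_lsig, s_avm, s_ahm, s_avh)
    return(list(loglik = ll, score = S, grad = colSums(S)))
  }

  if (mats$has_t) {
    gamma <- theta[id$gamma]
    rvm <- tanh(theta[id$avm])
    qv <- 2 * mats$V - 1
    eta_v <- drop(mats$Zv %*% gamma)
    wv <- qv * eta_v
    wm <- qm * eta_m
    r <- qv * qm * rvm
    P2 <- pbvnorm(wv, wm, r); P2[P2 < 1e-300] <- 1e-300
    ll <- sum(log(P2))
    if (!want_score && !grad_only) return(ll)
    om <- 1 - r * r
    g1 <- stats::dnorm(wv) * stats::pnorm((wm - r * wv) / sqrt(om)) / P2
    g2 <- stats::dnorm(wm) * stats::pnorm((wv - r * wm) / sqrt(om)) / P2
    gr <- dbvnorm(wv, wm, r) / P2
    if (grad_only) {
      g <- c(crossprod(mats$X, g2 * qm), crossprod(mats$Zv, g1 * qv),
             sum(gr * qv * qm * (1 - rvm^2)))
      return(list(loglik = ll, grad = g))
    }
    S <- cbind(mats$X * (g2 * qm), mats$Zv * (g1 * qv),
               gr * qv * qm * (1 - rvm^2))
    return(list(loglik = ll, score = S, grad = colSums(S)))
  }

  ## continuous endogenous regressor only
  delta <- theta[id$delta]
  sig <- exp(theta[id$lsig])
  rhm <- tanh(theta[id$ahm])
  e <- mats$h - drop(mats$Zh %*% delta)
  u <- e / sig
  cm <- sqrt(1 - rhm^2)
  wm <- qm * (eta_m + rhm * u) / cm
  P1 <- stats::pnorm(wm); P1[P1 < 1e-300] <- 1e-300
  ll <- sum(stats::dnorm(e, 0, sig, log = TRUE)) + sum(log(P1))
  if (!want_score && !grad_only) return(ll)
  g2 <- stats::dnorm(wm) / P1
  dl_e <- -e / sig^2 + g2 * qm * rhm / (cm * sig)
  dl_lsig <- (e^2 / sig^2 - 1) - g2 * qm * rhm * u / cm
  dwm_rhm <- qm * (u + (eta_m + rhm * u) * rhm / cm^2) / cm
  if (grad_only) {
    g <- c(crossprod(mats$X, g2 * qm / cm), crossprod(mats$Zh, -dl_e),
           sum(dl_lsig), sum(g2 * dwm_rhm * (1 - rhm^2)))
    return(list(loglik = ll, grad = g))
  }
  S <- cbind(mats$X * (g2 * qm / cm), mats$Zh * (-dl_e),
             dl_lsig, g2 * dwm_rhm * (1 - rhm^2))
  list(loglik = ll, score = S, grad = colSums(S))
}

#' Extended-probit log-likelihood
#'
#' Evaluates the joint log-likelihood at a packed parameter vector in the
#' unconstrained parameterisation (error correlations as `atanh(rho)`, the
#' continuous-equation SD as `log(sigma)`). The parameter layout is outcome
#' coefficients, treatment coefficients, continuous-equation coefficients,
#' `log(sigma)`, then `atanh(rho_vm)`, `atanh(rho_hm)`, `atanh(rho_vh)`
#' (only the components active in `spec`); see [erm_start()] for a packed
#' starting vector with names.
#'
#' @param params packed parameter vector.
#' @param table data.
#' @param spec an [erm_spec()].
#' @return the log-likelihood (\code{-Inf} at an invalid correlation
#'   configuration, never an error).
#' @export
erm_loglik <- function(params, table, spec) {
  mats <- erm_matrices(table, spec)
  if (length(params) != mats$n_par)
    stop_named("expected %d parameters, got %d", mats$n_par, length(params))
  erm_objective(params, mats, want_score = FALSE)
}

#' Staged starting values for the extended probit
#'
#' Separate single-equation fits (probit for the treatment and outcome
#' equations, OLS for the continuous equation) with all error correlations
#' started at zero.
#'
#' @inheritParams erm_loglik
#' @return named packed parameter vector.
#' @export
erm_start <- function(table, spec) {
  mats <- erm_matrices(table, spec)
  erm_start_mats(mats)
}

erm_start_mats <- function(mats) {
  th <- numeric(mats$n_par)
  th[mats$idx$beta] <- suppressWarnings(
    stats::glm.fit(mats$X, mats$M, family = stats::binomial("probit"))$coefficients)
  if (mats$has_t)
    th[mats$idx$gamma] <- suppressWarnings(
      stats::glm.fit(mats$Zv, mats$V, family = stats::binomial("probit"))$coefficients)
  if (mats$has_c) {
    ols <- stats::lm.fit(mats$Zh, mats$h)
    th[mats$idx$delta] <- ols$coefficients
    th[mats$idx$lsig] <- log(sqrt(mean(ols$residuals^2)))
  }
  names(th) <- mats$par_names
  th
}

#' Fit an extended probit model
#'
#' One-step maximum likelihood over all active equations. Optimisation uses
#' outer-product-of-scores (BHHH) Newton steps with backtracking line search
#' from staged single-equation starts, falling back to BFGS with the
#' analytic gradient if a step fails; convergence requires the
#' log-likelihood change to fall below `tol`. The reported covariance is the
#' robust sandwich `A^-1 B A^-1` (A the observed information by finite
#' differences of the analytic gradient, B the outer product of scores);
#' error-correlation inference is carried out on the Fisher-z scale and
#' back-transformed, so confidence limits always lie inside (-1, 1). A
#' warning is issued when the first-stage instruments are jointly weak
#' (Wald p > 0.05).
#'
#' @param table data.
#' @param spec an [erm_spec()].
#' @param tol convergence tolerance on the log-likelihood change.
#' @param maxit maximum number of BHHH iterations.
#' @param start optional packed starting vector (defaults to [erm_start()]).
#' @return object of class `erm_fit`.
#' @export
fit_erm <- function(table, spec, tol = 1e-8, maxit = 300L, start = NULL) {
  mats <- erm_matrices(table, spec)
  th <- if (is.null(start)) erm_start_mats(mats) else start
  if (anyNA(th))
    stop_named("starting values contain NA (rank-deficient design?)")

  ob <- erm_objective(th, mats, want_score = TRUE)
  if (!is.finite(ob$loglik)) stop_named("starting values give non-finite log-likelihood")
  ll <- ob$loglik
  trace <- ll
  converged <- FALSE
  for (it in seq_len(maxit)) {
    A <- crossprod(ob$score)
    step <- tryCatch(solve(A + diag(1e-8, ncol(A)), ob$grad),
                     error = function(e) ob$grad / sqrt(sum(ob$grad^2)))
    lam <- 1
    ok <- FALSE
    for (hh in 1:30) {
      thn <- th + lam * step
      lln <- erm_objective(thn, mats)
      if (is.finite(lln) && lln >= ll - 1e-12) { ok <- TRUE; break }
      lam <- lam / 2
    }
    if (!ok) break
    dl <- lln - ll
    th <- thn
    ll <- lln
    trace <- c(trace, ll)
    ob <- erm_objective(th, mats, want_score = TRUE)
    if (abs(dl) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    ## BHHH stalled: polish with BFGS on the analytic gradient
    op <- stats::optim(th, fn = function(t) -erm_objective(t, mats),
                       gr = function(t) -erm_objective(t, mats, grad_only = TRUE)$grad,
                       method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
    if (op$value <= -ll + tol) {
      th <- op$par
      ob <- erm_objective(th, mats, want_score = TRUE)
      ll <- ob$loglik
      trace <- c(trace, ll)
      converged <- TRUE
    } else {
      stop_named("extended probit did not converge in %d iterations (loglik trace: %s)",
                 maxit, paste(sprintf("%.4f", utils::tail(trace, 5)), collapse = " -> "))
    }
  }
  names(th) <- mats$par_names

  ## observed information by forward differences of the analytic gradient
  p <- mats$n_par
  H <- matrix(0, p, p)
  eps <- 1e-5
  g0 <- ob$grad
  for (j in seq_len(p)) {
    tp <- th
    tp[j] <- tp[j] + eps
    H[, j] <- (erm_objective(tp, mats, grad_only = TRUE)$grad - g0) / eps
  }
  H <- (H + t(H)) / 2
  A <- -H
  B <- crossprod(ob$score)
  Ainv <- tryCatch(solve(A), error = function(e) MASS::ginv(A))
  vcov_r <- Ainv %*% B %*% Ainv
  dimnames(vcov_r) <- dimnames(Ainv) <- list(mats$par_names, mats$par_names)

  rho_table <- erm_rho_table(th, vcov_r, mats)
  weak <- erm_weak_instruments(mats, spec)
  if (!is.null(weak) && any(weak$p_value > 0.05, na.rm = TRUE))
    warning("weak instruments: first-stage joint test p > 0.05 for ",
            paste(weak$equation[weak$p_value > 0.05], collapse = ", "))

  k <- p
  n <- length(mats$M)
  fit <- structure(list(
    theta = th,
    coefficients = list(
      outcome = stats::setNames(th[mats$idx$beta], colnames(mats$X)),
      treatment = if (mats$has_t) stats::setNames(th[mats$idx$gamma], colnames(mats$Zv)),
      continuous = if (mats$has_c) stats::setNames(th[mats$idx$delta], colnames(mats$Zh))),
    sigma_h = if (mats$has_c) exp(th[mats$idx$lsig]) else NULL,
    rho = rho_table$estimate,
    rho_table = rho_table,
    loglik = ll, aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
    vcov = vcov_r, vcov_model = Ainv, score = ob$score,
    n = n, iterations = it, converged = converged, trace = trace,
    first_stage_tests = weak,
    spec = spec), class = "erm_fit")
  fit
}

## Error-correlation estimates with Fisher-z (delta-method) inference,
## mirroring the published correlation-table layout.
erm_rho_table <- function(th, vcov_r, mats) {
  labels <- c(avm = "treatment_vs_outcome", ahm = "continuous_vs_outcome",
              avh = "continuous_vs_treatment")
  rows <- list()
  for (nm in names(labels)) {
    j <- mats$idx[[nm]]
    if (is.null(j)) next
    a <- th[j]
    se_a <- sqrt(vcov_r[j, j])
    rho <- tanh(a)
    rows[[nm]] <- data.frame(
      correlation = labels[[nm]],
      estimate = rho,
      robust_se = se_a * (1 - rho^2),
      z = a / se_a,
      p_value = 2 * stats::pnorm(-abs(a / se_a)),
      ci_lower = tanh(a - stats::qnorm(0.975) * se_a),
      ci_upper = tanh(a + stats::qnorm(0.975) * se_a))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$estimate <- as.numeric(out$estimate)
  structure(out, names_idx = names(rows))
}

## First-stage joint Wald tests of the excluded instruments.
erm_weak_instruments <- function(mats, spec) {
  rows <- list()
  if (mats$has_t) {
    g <- stats::glm.fit(mats$Zv, mats$V, family = stats::binomial("probit"))
    cf <- g$coefficients
    Xw <- sqrt(g$weights) * mats$Zv
    V <- tryCatch(solve(crossprod(Xw)), error = function(e) NULL)
    excl <- setdiff(spec$treatment_terms, spec$outcome_terms)
    idx <- which(instrument_columns(colnames(mats$Zv), excl))
    if (!is.null(V) && length(idx)) {
      w <- wald_joint(cf, V, idx)
      rows$treatment <- data.frame(equation = "treatment",
                                   statistic = w$statistic, df = w$df,
                                   p_value = w$p_value)
    }
  }
  if (mats$has_c) {
    ols <- stats::lm.fit(mats$Zh, mats$h)
    s2 <- sum(ols$residuals^2) / (length(ols$residuals) - ols$rank)
    V <- tryCatch(s2 * solve(crossprod(mats$Zh)), error = function(e) NULL)
    excl <- setdiff(spec$cont_terms, spec$outcome_terms)
    idx <- which(instrument_columns(colnames(mats$Zh), excl))
    if (!is.null(V) && length(idx)) {
      w <- wald_joint(ols$coefficients, V, idx)
      rows$continuous <- data.frame(equation = "continuous",
                                    statistic = w$statistic, df = w$df,
                                    p_value = w$p_value)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## map excluded instrument terms to design-matrix columns (factors expand)
instrument_columns <- function(colnames_z, excluded_terms) {
  sel <- rep(FALSE, length(colnames_z))
  for (tm in excluded_terms)
    sel <- sel | startsWith(colnames_z, tm)
  sel
}

#' @export
print.erm_fit <- function(x, ...) {
  cat(sprintf("<erm_fit> components=%s loglik=%.2f n=%d iters=%d\n",
              x$spec$components, x$loglik, x$n, x$iterations))
  print(x$rho_table, digits = 3)
  invisible(x)
}
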