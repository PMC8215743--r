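## Model-assessment machinery: discrimination (ROC AUC), calibration
## (Hosmer-Lemeshow, calibration belt, binned residuals, weak-calibration
## indices), and cross-validated shrinkage / overfitting.

check_probs <- function(p, strict = TRUE) {
  if (strict && (any(p <= 0) || any(p >= 1)))
    stop_named("probabilities must lie strictly inside (0, 1)")
  if (stats::sd(p) == 0)
    stop_named("degenerate input: constant predicted probabilities")
  invisible(p)
}

#' ROC area under the curve
#'
#' The probability that a randomly drawn event outranks a randomly drawn
#' non-event, with ties counted one half (Mann-Whitney).
#'
#' @param y binary outcome vector.
#' @param p predicted probabilities (any monotone score).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y, p) {
  if (length(unique(y)) < 2)
    stop_named("both outcome classes must be present to compute AUC")
  r <- rank(p)
  n1 <- sum(y == 1)
  n0 <- length(y) - n1
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups by quantiles of fitted risk (ties assigned to the lower group;
#' empty groups after ties are merged and flagged), computes
#' `sum((O - E)^2 / (E * (1 - E/n_g)))` and refers it to a chi-squared
#' distribution with `groups - 2` degrees of freedom.
#'
#' @param y binary outcomes.
#' @param p fitted probabilities.
#' @param groups number of risk groups (default 10).
#' @return list with `statistic`, `df`, `p_value`, `groups_used`, `merged`
#'   and the per-group table.
#' @export
hosmer_lemeshow <- function(y, p, groups = 10L) {
  n <- length(y)
  if (n < groups) stop_named("need at least as many observations as groups")
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1)))
  merged <- length(br) < groups + 1
  g <- cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  O <- tapply(y, g, sum)
  E <- tapply(p, g, sum)
  ng <- tapply(y, g, length)
  stat <- sum((O - E)^2 / (E * (1 - E / ng)))
  gu <- length(O)
  df <- max(gu - 2, 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       groups_used = gu, merged = merged,
       table = data.frame(n = as.integer(ng), observed = as.integer(O),
                          expected = as.numeric(E)))
}

#' Calibration belt
#'
#' Refits the outcome on polynomials of the logit of the predictions, the
#' degree (starting at 2) selected forward by likelihood-ratio tests; the
#' deviation p-value is the likelihood-ratio test of the selected
#' recalibration model against the identity line (slope 1, intercept 0). The
#' belt itself is the pointwise confidence band of the recalibration curve
#' evaluated on a probability grid.
#'
#' @param y binary outcomes.
#' @param p predicted probabilities, strictly inside (0, 1).
#' @param max_degree largest polynomial degree considered.
#' @param select_alpha forward-selection threshold for adding a degree.
#' @param conf pointwise confidence level of the belt.
#' @param grid_size number of grid points.
#' @return list with `degree`, `p_value` (deviation from identity), `df`,
#'   `statistic` and `belt` (grid, fitted curve and bounds).
#' @export
calibration_belt <- function(y, p, max_degree = 4L, select_alpha = 0.05,
                             conf = 0.95, grid_size = 100L) {
  if (length(y) < 100) stop_named("calibration belt needs n >= 100")
  check_probs(p)
  l <- qlogit(p)
  fits <- list()
  for (m in 2:max_degree) {
    fits[[m]] <- stats::glm(y ~ poly(l, m), family = stats::binomial())
    if (m > 2) {
      lr <- 2 * (as.numeric(stats::logLik(fits[[m]])) -
                   as.numeric(stats::logLik(fits[[m - 1]])))
      if (stats::pchisq(lr, 1, lower.tail = FALSE) > select_alpha) {
        m <- m - 1L
        break
      }
    }
    if (m == max_degree) break
  }
  sel <- fits[[m]]
  ll_sel <- as.numeric(stats::logLik(sel))
  ll_ident <- sum(stats::dbinom(y, 1, p, log = TRUE))
  stat <- 2 * (ll_sel - ll_ident)
  df <- length(stats::coef(sel))
  pval <- belt_deviation_p(max(stat, 0), m, select_alpha)
  grid_l <- seq(stats::quantile(l, 0.01), stats::quantile(l, 0.99),
                length.out = grid_size)
  pr <- stats::predict(sel, newdata = data.frame(l = grid_l), se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  belt <- data.frame(p_grid = stats::plogis(grid_l),
                     fitted = stats::plogis(pr$fit),
                     lower = stats::plogis(pr$fit - z * pr$se.fit),
                     upper = stats::plogis(pr$fit + z * pr$se.fit))
  list(degree = m, p_value = pval, statistic = stat, df = df, belt = belt)
}

## Null distribution of the deviation statistic given the forwardly selected
## degree. The degree-2 baseline contributes a chi-square(3) term (three
## constraints against the identity line); each forward step from degree
## k-1 to k was taken only because its LR increment exceeded the selection
## threshold, so conditional on the selected degree the increment is a
## chi-square(1) truncated below at qchisq(1 - select_alpha, 1). Ignoring the
## truncation (plain chi-square(degree + 1)) makes the test anticonservative
## whenever a degree above 2 is selected.
belt_deviation_p <- function(stat, degree, select_alpha) {
  if (degree <= 2) return(stats::pchisq(stat, 3, lower.tail = FALSE))
  cthr <- stats::qchisq(1 - select_alpha, 1)
  ## survival function of the chi-square(3) baseline term
  surv_base <- function(x) stats::pchisq(pmax(x, 0), 3, lower.tail = FALSE)
  ## density of one selection-truncated chi-square(1) increment
  f_trunc <- function(u)
    ifelse(u > cthr, stats::dchisq(u, 1) / select_alpha, 0)
  if (degree == 3) {
    return(stats::integrate(function(u) f_trunc(u) * surv_base(stat - u),
                            cthr, Inf, rel.tol = 1e-8)$value)
  }
  ## degree 4: convolve the two truncated increments, then the baseline
  f_sum2 <- function(s) vapply(s, function(si) {
    if (si <= 2 * cthr) return(0)
    stats::integrate(function(u) f_trunc(u) * f_trunc(si - u),
                     cthr, si - cthr, rel.tol = 1e-7)$value
  }, numeric(1))
  stats::integrate(function(s) f_sum2(s) * surv_base(stat - s),
                   2 * cthr, Inf, rel.tol = 1e-7)$value
}

#' Binned residuals
#'
#' Equal-count bins of the sorted fitted values; each bin reports the mean
#' fitted value, the mean residual (observed minus fitted) and the
#' `2 * sqrt(p * (1 - p) / n)` bound within which about 95% of bin means are
#' expected to fall under a well-calibrated model.
#'
#' @param y binary outcomes.
#' @param p fitted probabilities.
#' @param n_bins number of bins; default `floor(sqrt(n))`.
#' @return list with per-bin data.frame `bins` and overall `coverage`.
#' @export
binned_residuals <- function(y, p, n_bins = NULL) {
  n <- length(y)
  if (stats::sd(p) == 0) {
    ## constant fitted value: a single effective bin
    mp <- p[1]
    bins <- data.frame(mean_fitted = mp, mean_residual = mean(y) - mp,
                       bound = 2 * sqrt(mp * (1 - mp) / n), n_in_bin = n)
    return(list(bins = bins,
                coverage = mean(abs(bins$mean_residual) <= bins$bound)))
  }
  if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(n)))
  if (n < n_bins || n_bins < 2) stop_named("need n >= n_bins >= 2")
  ord <- order(p)
  bin <- ceiling(seq_along(ord) / (n / n_bins))
  bin <- pmin(bin, n_bins)
  idx <- split(ord, bin)
  bins <- do.call(rbind, lapply(idx, function(i) {
    mp <- mean(p[i])
    data.frame(mean_fitted = mp,
               mean_residual = mean(y[i] - p[i]),
               bound = 2 * sqrt(mp * (1 - mp) / length(i)),
               n_in_bin = length(i))
  }))
  rownames(bins) <- NULL
  list(bins = bins, coverage = mean(abs(bins$mean_residual) <= bins$bound))
}

#' Weak calibration indices
#'
#' Calibration-in-the-large (intercept of a logistic recalibration with the
#' prediction logit as fixed offset), calibration slope, and the
#' expected-to-observed event ratio.
#'
#' @param y binary outcomes.
#' @param p predicted probabilities strictly inside (0, 1).
#' @return list with `citl`, `slope`, `eo_ratio`.
#' @export
weak_calibration <- function(y, p) {
  check_probs(p)
  l <- qlogit(p)
  citl <- stats::coef(stats::glm(y ~ 1 + offset(l), family = stats::binomial()))[[1]]
  slope <- stats::coef(stats::glm(y ~ l, family = stats::binomial()))[["l"]]
  list(citl = citl, slope = slope, eo_ratio = sum(p) / sum(y))
}

#' Cross-validated shrinkage and overfitting
#'
#' Repeated k-fold cross-validation: per repetition the in-sample shrinkage
#' is `100 * (1 - calibration slope)` of the training predictions (averaged
#' over folds) and the out-of-sample shrinkage the same quantity on the
#' pooled held-out predictions; overfitting is their difference, averaged
#' over repetitions.
#'
#' @param table data.
#' @param spec a [model_spec()].
#' @param k number of folds.
#' @param reps number of repetitions.
#' @param seed RNG seed for the fold draws.
#' @return list with `shrink_in`, `shrink_out`, `overfit_pct` (percent).
#' @export
cv_shrinkage <- function(table, spec, k = 10L, reps = 1L, seed = 1L) {
  if (reps < 1 || k < 2) stop_named("need reps >= 1 and k >= 2")
  n <- nrow(table)
  y <- table[[spec$outcome]]
  set.seed(seed)
  res <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    folds <- NULL
    for (attempt in 1:10) {
      cand <- sample(rep(seq_len(k), length.out = n))
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(y[cand != f])) == 2 && length(unique(y[cand == f])) == 2,
        TRUE))
      if (ok) { folds <- cand; break }
    }
    if (is.null(folds))
      stop_named("could not draw folds with both classes after 10 attempts")
    slope_in <- numeric(k)
    p_out <- numeric(n)
    for (f in seq_len(k)) {
      tr <- table[folds != f, , drop = FALSE]
      fit <- fit_binary(tr, spec)
      p_tr <- clamp_prob(fit$fitted)
      slope_in[f] <- weak_calibration(y[folds != f], p_tr)$slope
      p_out[folds == f] <- clamp_prob(as.numeric(
        stats::predict(fit$model, newdata = table[folds == f, , drop = FALSE],
                       type = "response")))
    }
    slope_out <- weak_calibration(y, p_out)$slope
    res[r, ] <- c(100 * (1 - mean(slope_in)), 100 * (1 - slope_out))
  }
  out <- colMeans(res)
  list(shrink_in = out[1], shrink_out = out[2],
       overfit_pct = out[2] - out[1])
}

clamp_prob <- function(p, eps = 1e-10) pmin(pmax(p, eps), 1 - eps)

#' Development / validation split report
#'
#' Fits the model on a random development half and computes CITL, slope, AUC
#' and the E:O ratio on each half with the development-fitted model.
#'
#' @param table data.
#' @param spec a [model_spec()].
#' @param split development fraction.
#' @param seed RNG seed for the split.
#' @return list with `development` and `validation` index lists and the
#'   development-half `fit`.
#' @export
dev_val_report <- function(table, spec, split = 0.5, seed = 1L) {
  n <- nrow(table)
  y <- table[[spec$outcome]]
  set.seed(seed)
  dev_idx <- NULL
  for (attempt in 1:10) {
    cand <- sample.int(n) <= round(split * n)
    if (length(unique(y[cand])) == 2 && length(unique(y[!cand])) == 2) {
      dev_idx <- cand
      break
    }
  }
  if (is.null(dev_idx))
    stop_named("could not draw a split with both classes in each half")
  fit <- fit_binary(table[dev_idx, , drop = FALSE], spec)
  index_on <- function(rows) {
    p <- clamp_prob(as.numeric(stats::predict(
      fit$model, newdata = table[rows, , drop = FALSE], type = "response")))
    wc <- weak_calibration(y[rows], p)
    list(citl = wc$citl, slope = wc$slope, auc = roc_auc(y[rows], p),
         eo_ratio = wc$eo_ratio, n = sum(rows))
  }
  list(development = index_on(dev_idx), validation = index_on(!dev_idx),
       fit = fit)
}

#' Assemble a full calibration report for a fitted model
#'
#' @param fit a `fit_result` (or any object with `fitted`, `aic`, `bic`).
#' @param y observed binary outcomes aligned with `fit$fitted`.
#' @param belt compute the calibration belt (needs probabilities strictly
#'   inside (0,1)).
#' @return list mirroring a performance-table column: AUC, H-L, belt,
#'   binned-residual coverage, CITL/slope/E:O, AIC/BIC.
#' @export
calibration_report <- function(fit, y, belt = TRUE) {
  p <- fit$fitted
  pc <- clamp_prob(p)
  hl <- hosmer_lemeshow(y, p)
  wc <- weak_calibration(y, pc)
  br <- binned_residuals(y, p)
  bt <- if (belt) tryCatch(calibration_belt(y, pc), error = function(e) NULL) else NULL
  list(auc = roc_auc(y, p),
       hl_stat = hl$statistic, hl_p = hl$p_value,
       belt_degree = if (is.null(bt)) NA_integer_ else bt$degree,
       belt_p = if (is.null(bt)) NA_real_ else bt$p_value,
       citl = wc$citl, slope = wc$slope, eo_ratio = wc$eo_ratio,
       binned_coverage = br$coverage,
       aic = fit$aic, bic = fit$bic, n = length(y))
}
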