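# Step 4: climate-elasticity models (CEMs) fitted to pre-fire annual
# anomalies, selected by BIC, significance-tested, and used to split the
# observed 5-year flow change into a climate-expected part and a
# fire-attributed remainder (Delta Q_dist = Delta Q_obs - Delta Q_clim).

CEM_PREDICTORS <- list(CEM1 = "P",
                       CEM2 = c("P", "PET"),
                       CEM3 = c("P", "sigma2_Pm"),
                       CEM4 = c("P", "SWE"))

# Anomaly-form least squares without intercept; Gaussian likelihood with
# variance SSE/n so BIC is computable from the fit alone.
fit_one_cem <- function(id, annual, predictors) {
  dq <- annual$Q - mean(annual$Q)
  n <- length(dq)
  X <- as.matrix(annual[predictors])
  X <- sweep(X, 2, colMeans(X))
  colnames(X) <- predictors
  fit <- tryCatch(lm(dq ~ 0 + X), error = function(e) NULL)
  if (is.null(fit) || any(is.na(coef(fit))))
    return(structure(list(id = id, fittable = FALSE,
                          reason = "rank-deficient predictors"),
                     class = "cem_fit"))
  sse <- sum(fit$residuals ^ 2)
  sigma2 <- sse / n
  loglik <- if (sigma2 > 0) -n / 2 * (log(2 * pi * sigma2) + 1) else Inf
  k <- length(predictors) + 1  # coefficients + residual variance
  bic <- if (is.finite(loglik)) -2 * loglik + k * log(n) else -Inf
  cf <- setNames(coef(fit), predictors)
  structure(list(id = id, fittable = TRUE, predictors = predictors,
                 coefficients = cf, sse = sse, n = n, k = k,
                 loglik = loglik, bic = bic, lm = fit),
            class = "cem_fit")
}

#' Fit the candidate climate-elasticity models
#'
#' Fits CEM1 (dP), CEM2 (dP, dPET), CEM3 (dP, d sigma2_Pm) and CEM4
#' (dP, dSWE) by least squares on pre-fire annual anomalies (each year's
#' value minus the pre-fire mean), with no intercept -- the anomaly form has
#' none. Coefficients are elasticities in mm of flow per mm of predictor
#' (per mm2 for the variance term). BIC is `-2 ln L_k + k ln n` with a
#' Gaussian likelihood whose variance is SSE/n.
#'
#' @param annual Data frame of pre-fire annual records with columns `Q`,
#'   `P` and any of `PET`, `sigma2_Pm`, `SWE` (see [prefire_annual()]).
#'   With fewer than 4 years only CEM1 is attempted; candidates whose
#'   predictors are missing or collinear are flagged unfittable.
#' @return Named list of `cem_fit` objects (`CEM1` .. `CEM4`).
#' @export
fit_cems <- function(annual) {
  stop_if(!all(c("Q", "P") %in% names(annual)),
          "annual records need at least Q and P")
  n <- nrow(annual)
  stop_if(n < 3, "need at least 3 pre-fire years")
  ids <- if (n < 4) "CEM1" else names(CEM_PREDICTORS)
  fits <- lapply(ids, function(id) {
    preds <- CEM_PREDICTORS[[id]]
    if (!all(preds %in% names(annual)))
      return(structure(list(id = id, fittable = FALSE,
                            reason = paste("missing predictor(s):",
                                           paste(setdiff(preds, names(annual)),
                                                 collapse = ", "))),
                       class = "cem_fit"))
    fit_one_cem(id, annual, preds)
  })
  out <- setNames(fits, ids)
  if (n < 4)
    for (id in setdiff(names(CEM_PREDICTORS), ids))
      out[[id]] <- structure(list(id = id, fittable = FALSE,
                                  reason = "insufficient pre-fire years"),
                             class = "cem_fit")
  out[names(CEM_PREDICTORS)]
}

#' Select the best CEM by BIC
#'
#' Minimum-BIC candidate among the fittable ones; ties go to the model with
#' fewer parameters, then to the lower-numbered model (CEM1 first).
#'
#' @param fits Output of [fit_cems()].
#' @return The selected `cem_fit`.
#' @export
select_best_cem <- function(fits) {
  ok <- Filter(function(f) isTRUE(f$fittable), fits)
  stop_if(length(ok) == 0, "no fittable CEM candidate")
  bic <- vapply(ok, `[[`, numeric(1), "bic")
  k <- vapply(ok, `[[`, numeric(1), "k")
  ord <- order(bic, k, match(names(ok), names(CEM_PREDICTORS)))
  ok[[ord[1]]]
}

#' Significance of a fitted CEM
#'
#' Multi-predictor CEMs are tested with the overall regression F-test
#' (no-intercept form: `F = (SSR/p) / (SSE/(n - p))` on `(p, n - p)`
#' degrees of freedom); the one-parameter CEM1 uses the coefficient t-test,
#' which remains available at sample sizes where the F statistic has too
#' few degrees of freedom.
#'
#' @param fit A fittable `cem_fit`.
#' @param alpha Significance level.
#' @return List with `test` ("F", "t" or "untestable"), `statistic`,
#'   `p_value`, `significant`.
#' @export
cem_significance <- function(fit, alpha = 0.05) {
  stop_if(!isTRUE(fit$fittable), "fit is not fittable")
  p <- length(fit$predictors)
  df_res <- fit$n - p
  if (df_res < 1 || fit$sse <= 0)
    return(list(test = "untestable", statistic = NA_real_,
                p_value = NA_real_, significant = NA))
  if (p == 1) {
    sm <- summary(fit$lm)$coefficients
    tval <- sm[1, "t value"]
    pval <- sm[1, "Pr(>|t|)"]
    list(test = "t", statistic = tval, p_value = pval,
         significant = pval < alpha)
  } else {
    y <- fit$lm$model[[1]]
    ssr <- sum(y ^ 2) - fit$sse  # no-intercept decomposition
    f <- (ssr / p) / (fit$sse / df_res)
    pval <- pf(f, p, df_res, lower.tail = FALSE)
    list(test = "F", statistic = f, p_value = pval,
         significant = pval < alpha)
  }
}

#' Climate-expected flow change
#'
#' Applies the fitted elasticities to the observed post-minus-pre climate
#' deltas: `Delta Q_clim = sum_j beta_j * delta_j`. The anomaly form has no
#' intercept, so all-zero deltas give exactly zero.
#'
#' @param fit A fittable `cem_fit`.
#' @param deltas A [window_summary()] or a named vector of deltas covering
#'   the fit's predictors (`P`, `PET`, `sigma2_Pm`, `SWE`).
#' @return `Delta Q_clim` in mm/yr.
#' @export
predict_dq_clim <- function(fit, deltas) {
  stop_if(!isTRUE(fit$fittable), "fit is not fittable")
  if (inherits(deltas, "window_summary")) deltas <- deltas$delta
  missing <- setdiff(fit$predictors, names(deltas))
  stop_if(length(missing) > 0,
          "deltas missing predictor(s): ", paste(missing, collapse = ", "))
  sum(fit$coefficients * deltas[fit$predictors])
}

#' Attribute the observed flow change to fire vs. climate
#'
#' `Delta Q_dist = Delta Q_obs - Delta Q_clim`: the part of the observed
#' 5-year flow change the climate-elasticity model cannot explain,
#' presumed fire-caused when the watershed's BAR reaches the critical
#' threshold and a flow or yield disturbance was detected.
#'
#' @param dq_obs Observed flow change (mm/yr, post minus pre 5-year mean).
#' @param dq_clim Climate-expected change from [predict_dq_clim()] (mm/yr).
#' @param q_pre Pre-fire 5-year mean annual flow (mm/yr); must be positive
#'   for the percent forms, otherwise they are suppressed and flagged.
#' @param bar Watershed BAR (fraction) for the eligibility flag; optional.
#' @param bar_t Critical BAR threshold (fraction; default 0.19).
#' @return An `attribution` list: `dq_obs`, `dq_clim`, `dq_dist` (mm/yr),
#'   their percent forms relative to `q_pre` (`NA` with `pct_suppressed =
#'   TRUE` when `q_pre <= 0`), and `eligible` (`bar >= bar_t`).
#' @export
attribute_disturbance <- function(dq_obs, dq_clim, q_pre,
                                  bar = NA_real_, bar_t = 0.19) {
  dq_dist <- dq_obs - dq_clim
  ok <- is.finite(q_pre) && q_pre > 0
  pct <- function(x) if (ok) 100 * x / q_pre else NA_real_
  structure(list(dq_obs = dq_obs, dq_clim = dq_clim, dq_dist = dq_dist,
                 dq_obs_pct = pct(dq_obs), dq_clim_pct = pct(dq_clim),
                 dq_dist_pct = pct(dq_dist), q_pre = q_pre,
                 pct_suppressed = !ok,
                 eligible = if (is.na(bar)) NA else bar >= bar_t,
                 bar = bar, bar_t = bar_t),
            class = "attribution")
}

#' @export
print.cem_fit <- function(x, ...) {
  if (!isTRUE(x$fittable)) {
    cat(sprintf("<cem_fit %s> unfittable: %s\n", x$id, x$reason))
  } else {
    cat(sprintf("<cem_fit %s> n = %d, BIC = %.2f; coefficients: %s\n",
                x$id, x$n, x$bic,
                paste(sprintf("%s = %.3f", names(x$coefficients),
                              x$coefficients), collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.attribution <- function(x, ...) {
  fmt <- function(v, p) if (is.na(p)) sprintf("%+.1f mm", v)
    else sprintf("%+.1f mm (%+.1f%%)", v, p)
  cat(sprintf("<attribution> dQ_obs %s = dQ_clim %s + dQ_dist %s\n",
              fmt(x$dq_obs, x$dq_obs_pct), fmt(x$dq_clim, x$dq_clim_pct),
              fmt(x$dq_dist, x$dq_dist_pct)))
  if (!is.na(x$eligible))
    cat(sprintf("  BAR %.1f%% %s BAR_t %.1f%%: %sfire-attribution eligible\n",
                100 * x$bar, if (x$eligible) ">=" else "<", 100 * x$bar_t,
                if (x$eligible) "" else "not "))
  invisible(x)
}
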