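# The cross-watershed predictor table consumed by the influence module.
# The reference analysis used 49 predictors drawn from families (fire size
# and severity, watershed geometry, climate levels/changes/variability,
# topography, land cover) without enumerating them; this manifest rebuilds
# those families compactly and is versioned here, not asserted as the
# original list.

FEATURE_MANIFEST <- c(
  # fire
  "BAR", "frac_unburned", "frac_low", "frac_moderate", "frac_high",
  "frac_greenness",
  # geometry & topography
  "area_km2", "perimeter_km", "compactness", "elevation_m", "slope",
  # land cover
  "lc_forest", "lc_barren", "lc_urban", "lc_other",
  # climate: 5-yr pre/post levels, deltas, percent deltas
  "P_pre", "P_post", "dP", "dP_pct",
  "PET_pre", "PET_post", "dPET", "dPET_pct",
  "SWE_pre", "SWE_post", "dSWE",
  "sigma2_Pm_pre", "sigma2_Pm_post", "dsigma2_Pm")

#' Build the per-watershed feature table
#'
#' One row per cohort case: fire variables (BAR and watershed-area severity
#' fractions), geometry, topography, land cover, and 5-year pre/post climate
#' summaries with their changes, plus the response columns `dQ` (mm/yr),
#' `dQ_pct` and `Q_pre`. Response columns and `id` are excluded from
#' boosting by [fit_gbm_influence()] callers via [feature_predictors()].
#'
#' @param cohort List of `synthetic_case` objects ([generate_cohort()]).
#' @return Data frame with `id`, the predictor manifest columns, and the
#'   response columns.
#' @export
feature_table <- function(cohort) {
  rows <- lapply(cohort, function(cs) {
    ws <- window_summary(cs$monthly, cs$fire$date)
    af <- cs$fire$area_fractions
    lc <- cs$attrs$landcover
    data.frame(
      id = cs$id,
      BAR = cs$fire$bar,
      frac_unburned = af[["unburned"]], frac_low = af[["low"]],
      frac_moderate = af[["moderate"]], frac_high = af[["high"]],
      frac_greenness = af[["greenness"]],
      area_km2 = cs$attrs$area_km2, perimeter_km = cs$attrs$perimeter_km,
      compactness = cs$attrs$compactness,
      elevation_m = cs$attrs$elevation_m, slope = cs$attrs$slope,
      lc_forest = lc[["forest"]], lc_barren = lc[["barren"]],
      lc_urban = lc[["urban"]], lc_other = lc[["other"]],
      P_pre = ws$pre[["P"]], P_post = ws$post[["P"]],
      dP = ws$delta[["P"]], dP_pct = ws$delta_pct[["P"]],
      PET_pre = ws$pre[["PET"]], PET_post = ws$post[["PET"]],
      dPET = ws$delta[["PET"]], dPET_pct = ws$delta_pct[["PET"]],
      SWE_pre = ws$pre[["SWE"]], SWE_post = ws$post[["SWE"]],
      dSWE = ws$delta[["SWE"]],
      sigma2_Pm_pre = ws$pre[["sigma2_Pm"]],
      sigma2_Pm_post = ws$post[["sigma2_Pm"]],
      dsigma2_Pm = ws$delta[["sigma2_Pm"]],
      dQ = ws$delta[["Q"]], dQ_pct = ws$delta_pct[["Q"]],
      Q_pre = ws$pre[["Q"]],
      row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Predictor columns of a feature table
#'
#' Drops the identifier and response columns, leaving the boosting inputs.
#'
#' @param features Output of [feature_table()].
#' @return Data frame of predictors only.
#' @export
feature_predictors <- function(features) {
  features[setdiff(names(features), c("id", "dQ", "dQ_pct", "Q_pre"))]
}
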