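# Derived variables consumed by the framework: Hamon PET, Gravelius
# compactness, burned-area ratio, and 5-year pre/post-fire window summaries.

#' Saturation vapor pressure (Magnus form)
#'
#' `e_sat = 0.6108 * exp(17.27 T / (T + 237.3))` in kPa, the standard
#' companion to Hamon's PET formula.
#'
#' @param t_c Air temperature (degrees C).
#' @return Saturation vapor pressure (kPa).
#' @export
magnus_esat <- function(t_c) 0.6108 * exp(17.27 * t_c / (t_c + 237.3))

#' Hamon potential evapotranspiration
#'
#' `PET = 29.8 * Hr_day * e_sat(T) / (T + 273.2)` in mm per day, with
#' daylight hours `Hr_day` and saturation vapor pressure `e_sat` in kPa.
#'
#' @param t_c Mean air temperature (degrees C); must exceed -273.2.
#' @param hr_day Daylight hours, in `[0, 24]`.
#' @param esat Saturation vapor pressure function of temperature (kPa);
#'   defaults to the Magnus form ([magnus_esat()]).
#' @return PET (mm per day), non-negative.
#' @examples
#' hamon_pet(20, 12)  # about 2.85 mm/d
#' @export
hamon_pet <- function(t_c, hr_day, esat = magnus_esat) {
  stop_if(any(t_c <= -273.2), "temperature must exceed -273.2 C")
  stop_if(any(hr_day < 0 | hr_day > 24), "hr_day must be in [0, 24]")
  29.8 * hr_day * esat(t_c) / (t_c + 273.2)
}

#' Gravelius compactness coefficient
#'
#' Ratio of the watershed perimeter to the perimeter of a circle with the
#' same area: `C = Pm / (2 * sqrt(pi * A))`. Equals 1 for a circle and
#' exceeds 1 for any other shape; a value below 1 indicates inconsistent
#' perimeter/area measurements and raises a warning.
#'
#' @param perimeter_km Perimeter (km), > 0.
#' @param area_km2 Area (km2), > 0.
#' @return Dimensionless compactness.
#' @export
gravelius_compactness <- function(perimeter_km, area_km2) {
  stop_if(any(perimeter_km <= 0) || any(area_km2 <= 0),
          "perimeter and area must be > 0")
  cc <- perimeter_km / (2 * sqrt(pi * area_km2))
  if (any(cc < 1 - 1e-9))
    warning("compactness < 1: perimeter/area are geometrically inconsistent")
  cc
}

#' Burned-area ratio
#'
#' BAR = burned area / drainage area, the key relative fire-size measure.
#' Watersheds with BAR >= 1 % form the plenary analysis set; BAR >= 19 %
#' marks the attribution subset in the reference analysis.
#'
#' @param event A [fire_event()].
#' @param attrs A [watershed_attrs()].
#' @return BAR as a fraction in `[0, 1]`.
#' @export
burned_area_ratio <- function(event, attrs) {
  burned <- if (!is.null(event$burned_area_km2) &&
                !is.na(event$burned_area_km2)) {
    event$burned_area_km2
  } else {
    event$bar * attrs$area_km2
  }
  stop_if(burned > attrs$area_km2 + 1e-9,
          "burned area exceeds drainage area")
  burned / attrs$area_km2
}

#' Aggregate a daily series to calendar months
#'
#' Precipitation, PET and flow are summed; temperature and SWE are averaged.
#'
#' @param daily Data frame with a `date` column (Date) and any of
#'   `P_mm`, `T_C`, `Hr_day`, `PET_mm`, `SWE_mm`, `Q_mm`.
#' @return Data frame with one row per calendar month, `date` set to the
#'   first of the month.
#' @export
monthly_series <- function(daily) {
  stop_if(!inherits(daily$date, "Date"), "daily$date must be Date")
  key <- format(daily$date, "%Y-%m-01")
  out <- data.frame(date = as.Date(sort(unique(key))))
  sums <- intersect(c("P_mm", "PET_mm", "Q_mm", "Q_nofire_mm"), names(daily))
  means <- intersect(c("T_C", "SWE_mm", "Hr_day"), names(daily))
  for (v in sums)
    out[[v]] <- as.numeric(tapply(daily[[v]], key, sum))
  for (v in means)
    out[[v]] <- as.numeric(tapply(daily[[v]], key, mean))
  out
}

# First day of the calendar month containing x.
month_floor <- function(x) as.Date(format(as.Date(x), "%Y-%m-01"))

# Index of the fire month within a monthly series; the fire month opens the
# post window.
window_indices <- function(dates, fire_date, k = 60) {
  fm <- month_floor(fire_date)
  i0 <- match(fm, dates)
  stop_if(is.na(i0), "fire month not present in the monthly series")
  n_pre <- i0 - 1
  n_post <- length(dates) - i0 + 1
  stop_if(n_pre < k || n_post < k,
          sprintf("need %d months each side of the fire; have %d pre, %d post",
                  k, n_pre, n_post))
  list(pre = (i0 - k):(i0 - 1), post = i0:(i0 + k - 1))
}

#' Five-year pre/post-fire window summary
#'
#' Aggregates exactly 60 calendar months before the fire month and 60 from
#' the fire month onward (the fire month belongs to the post window, because
#' disturbance is sought in the year following the fire). Reports 5-year
#' mean annual precipitation, PET, SWE and flow, the variance of the 60
#' monthly precipitation totals, and their post-minus-pre deltas in absolute
#' and percent form.
#'
#' @param monthly Output of [monthly_series()]; needs `P_mm`, `Q_mm` and
#'   optionally `PET_mm`, `SWE_mm`.
#' @param fire_date Fire date (coerced to its calendar month).
#' @return A `window_summary` list with elements `pre`, `post`, `delta`,
#'   `delta_pct` (each named vectors over `P`, `PET`, `SWE`, `Q`,
#'   `sigma2_Pm`) and `pct_undefined` naming variables whose pre-window mean
#'   is zero (percent form suppressed, not silently dropped).
#' @export
window_summary <- function(monthly, fire_date) {
  idx <- window_indices(monthly$date, fire_date)
  vars <- c(P = "P_mm", PET = "PET_mm", SWE = "SWE_mm", Q = "Q_mm")
  vars <- vars[vars %in% names(monthly)]
  one <- function(rows) {
    out <- vapply(vars, function(v) {
      x <- monthly[[v]][rows]
      if (v == "SWE_mm") mean(x) else sum(x) / 5  # mean annual total
    }, numeric(1))
    c(out, sigma2_Pm = var(monthly$P_mm[rows]))
  }
  pre <- one(idx$pre)
  post <- one(idx$post)
  delta <- post - pre
  pct <- ifelse(pre != 0, 100 * delta / pre, NA_real_)
  names(pct) <- names(delta)
  structure(list(pre = pre, post = post, delta = delta, delta_pct = pct,
                 pct_undefined = names(pre)[pre == 0],
                 fire_month = month_floor(fire_date)),
            class = "window_summary")
}

#' Pre-fire annual records for climate-elasticity fitting
#'
#' Splits the 60 pre-fire months into five consecutive 12-month
#' (fire-anniversary) years and returns annual totals of flow, precipitation
#' and PET, mean SWE, and the variance of the 12 monthly precipitation
#' totals within each year.
#'
#' @inheritParams window_summary
#' @return Data frame with columns `year`, `Q`, `P`, `PET`, `SWE`,
#'   `sigma2_Pm` (one row per pre-fire year, oldest first). Columns absent
#'   from `monthly` are omitted.
#' @export
prefire_annual <- function(monthly, fire_date) {
  idx <- window_indices(monthly$date, fire_date)$pre
  grp <- rep(1:5, each = 12)
  vars <- c(Q = "Q_mm", P = "P_mm", PET = "PET_mm", SWE = "SWE_mm")
  vars <- vars[vars %in% names(monthly)]
  out <- data.frame(year = 1:5)
  for (nm in names(vars)) {
    x <- monthly[[vars[[nm]]]][idx]
    out[[nm]] <- if (nm == "SWE") as.numeric(tapply(x, grp, mean))
                 else as.numeric(tapply(x, grp, sum))
  }
  out$sigma2_Pm <- as.numeric(tapply(monthly$P_mm[idx], grp, var))
  out
}
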