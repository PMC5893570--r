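# Synthetic watershed generator: seeded daily weather, degree-day snowpack,
# elasticity-driven flow with an injected, threshold-gated fire effect.
# Every stochastic step draws from one explicit seed so cohorts are
# reproducible and counterfactual (no-fire) runs are exactly paired.

season_of <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4, 1)[m]  # DJF, MAM, JJA, SON
}

day_of_year <- function(dates) as.integer(format(dates, "%j"))

#' Generate a daily weather series
#'
#' Precipitation occurrence follows a two-state Markov chain whose
#' stationary wet-day probability varies by season; wet-day depths are
#' gamma. Temperature is a sinusoid (warmest around mid-July) with Gaussian
#' noise. Daylight hours are a deterministic sinusoid peaking at the summer
#' solstice.
#'
#' @param params A [weather_params()].
#' @param n_years Number of years to simulate (>= 10; the downstream
#'   analysis needs two 5-year windows).
#' @param seed Integer seed.
#' @param start_year First calendar year (default 1990).
#' @return Data frame with columns `date`, `P_mm`, `T_C`, `Hr_day`.
#' @export
generate_daily_weather <- function(params, n_years, seed, start_year = 1990) {
  stopifnot(inherits(params, "weather_params"))
  stop_if(n_years < 10,
          "n_years must be >= 10 (two 5-year windows are required)")
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
               by = "day")
  nd <- length(dates)
  doy <- day_of_year(dates)
  p <- params$p_wet[season_of(dates)]
  r <- params$wet_persistence
  # Markov chain: P(wet | wet) = p + r(1-p), P(wet | dry) = p(1-r); the
  # stationary wet probability is p for any r in [0, 1).
  u <- runif(nd)
  wet <- logical(nd)
  wet[1] <- u[1] < p[1]
  p11 <- p + r * (1 - p)
  p01 <- p * (1 - r)
  for (i in 2:nd) wet[i] <- u[i] < if (wet[i - 1]) p11[i] else p01[i]
  depth_mean <- params$wet_depth_mean *
    (1 + params$precip_trend) ^ (as.integer(format(dates, "%Y")) - start_year)
  P <- numeric(nd)
  nwet <- sum(wet)
  if (nwet > 0 && params$wet_depth_mean > 0) {
    sh <- params$wet_depth_shape
    P[wet] <- rgamma(nwet, shape = sh, rate = sh / depth_mean[wet])
  }
  T_C <- params$t_mean -
    params$t_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    rnorm(nd, sd = params$t_noise_sd)
  # cos peak shifted so the warmest day lands near mid-July (doy ~ 198)
  Hr <- 12 + params$daylight_amplitude * sin(2 * pi * (doy - 80) / 365.25)
  Hr <- pmin(pmax(Hr, 0), 24)
  data.frame(date = dates, P_mm = P, T_C = T_C, Hr_day = Hr)
}

#' Simulate snowpack with a degree-day model
#'
#' Precipitation falling at temperatures below `snow_threshold` accumulates
#' as snow-water equivalent; melt is `degree_day_factor * (T - threshold)`
#' on days above the threshold, capped by the available pack.
#'
#' @param series Daily series with `P_mm` and `T_C`.
#' @param params A [hydro_params()].
#' @return The series with columns `SWE_mm` (end-of-day pack) and `melt_mm`
#'   added.
#' @export
simulate_snowpack <- function(series, params) {
  stopifnot(all(c("P_mm", "T_C") %in% names(series)))
  thr <- params$snow_threshold
  snow <- ifelse(series$T_C < thr, series$P_mm, 0)
  pot_melt <- pmax(series$T_C - thr, 0) * params$degree_day_factor
  n <- nrow(series)
  swe <- melt <- numeric(n)
  pack <- 0
  for (i in seq_len(n)) {
    pack <- pack + snow[i]
    melt[i] <- min(pot_melt[i], pack)
    pack <- pack - melt[i]
    swe[i] <- pack
  }
  series$SWE_mm <- swe
  series$melt_mm <- melt
  series
}

# Fire-effect multiplier per day: 1 outside the effect window, otherwise
# 1 + coefficient * frac_modhigh (optionally ramping linearly to 1).
fire_multiplier <- function(dates, fire, effect) {
  m <- rep(1, length(dates))
  if (is.null(fire)) return(m)
  bar <- fire$bar
  fmh <- fire$area_fractions[["moderate"]] + fire$area_fractions[["high"]]
  if (bar < effect$activation_bar || fmh <= 0) return(m)
  t0 <- as.Date(fire$date)
  dur <- effect$duration_years
  t1 <- if (dur == round(dur)) {
    seq(t0, by = sprintf("%d years", as.integer(dur)), length.out = 2)[2]
  } else {
    t0 + round(dur * 365.25)
  }
  on <- dates >= t0 & dates < t1
  amp <- effect$coefficient * fmh
  if (effect$decay == "linear") {
    frac <- as.numeric(dates[on] - t0) / as.numeric(t1 - t0)
    m[on] <- 1 + amp * (1 - frac)
  } else {
    m[on] <- 1 + amp
  }
  m
}

#' Simulate daily river flow
#'
#' Effective water input (rain plus snowmelt) is routed through a linear
#' reservoir and scaled so that annual flow responds to annual
#' precipitation and PET with the configured log-log elasticities. Additive
#' Gaussian daily noise (truncated at zero) is applied, and finally the
#' fire effect multiplies flow during the effect window when BAR reaches
#' the activation threshold. Because the effect is a deterministic
#' multiplier applied last, a run with `effect$coefficient = 0` under the
#' same seed is an exact no-fire counterfactual.
#'
#' @param series Daily series with `P_mm`, `T_C`, `Hr_day` and snow columns
#'   from [simulate_snowpack()] (added automatically when missing).
#' @param hydro A [hydro_params()].
#' @param fire A [fire_event()] or `NULL` for an unburned run.
#' @param effect A [fire_effect_params()].
#' @param seed Integer seed for the flow noise.
#' @return The series with `PET_mm`, `Q_nofire_mm` (counterfactual) and
#'   `Q_mm` added; attribute `truth` records the injected effect.
#' @export
simulate_flow <- function(series, hydro, fire = NULL,
                          effect = fire_effect_params(), seed = 1) {
  if (!"SWE_mm" %in% names(series)) series <- simulate_snowpack(series, hydro)
  if (!is.null(fire)) {
    fd <- as.Date(fire$date)
    stop_if(fd < min(series$date) || fd > max(series$date),
            "fire date falls outside the simulated series")
  }
  set.seed(seed)
  series$PET_mm <- hamon_pet(series$T_C, series$Hr_day)
  thr <- hydro$snow_threshold
  rain <- ifelse(series$T_C < thr, 0, series$P_mm)
  w <- rain + series$melt_mm
  n <- nrow(series)
  # linear-reservoir smoothing of the input (unit gain at steady state)
  k <- hydro$recession
  base <- numeric(n)
  prev <- mean(w)
  for (i in seq_len(n)) {
    prev <- k * prev + (1 - k) * w[i]
    base[i] <- prev
  }
  yr <- format(series$date, "%Y")
  p_ann <- tapply(series$P_mm, yr, sum)
  pet_ann <- tapply(series$PET_mm, yr, sum)
  w_ann <- tapply(w, yr, sum)
  # scale each year so annual flow is proportional to P^eps_p * PET^eps_pet
  # regardless of snow carry-over or routing memory; the reservoir only
  # shapes the within-year distribution
  p_fac <- if (mean(p_ann) > 0) (p_ann / mean(p_ann)) ^ hydro$eps_p
           else rep(1, length(p_ann))
  f_yr <- p_fac * (pet_ann / mean(pet_ann)) ^ hydro$eps_pet
  rel_w <- ifelse(w_ann > 0, w_ann / mean(w_ann), 1)
  q0 <- hydro$runoff_coef * base * as.numeric((f_yr / rel_w)[yr])
  q0 <- pmax(q0 + rnorm(n, sd = hydro$flow_noise_sd), 0)
  mult <- fire_multiplier(series$date, fire, effect)
  series$Q_nofire_mm <- q0
  series$Q_mm <- q0 * mult
  fmh <- if (is.null(fire)) 0 else
    fire$area_fractions[["moderate"]] + fire$area_fractions[["high"]]
  active <- !is.null(fire) && fire$bar >= effect$activation_bar && fmh > 0
  attr(series, "truth") <- list(
    effect_active = active,
    effect_frac = if (active) effect$coefficient * fmh else 0,
    eps_p = hydro$eps_p, eps_pet = hydro$eps_pet)
  series
}

#' Construct a fire event
#'
#' Severity fractions are expressed over the burned area and must sum to 1;
#' watershed-area fractions per class are `mix * bar`.
#'
#' @param date Fire date.
#' @param bar Burned-area-to-drainage-area ratio, in `[0, 1]`.
#' @param severity_mix Named fractions over the burned area; any of
#'   `unburned`, `low`, `moderate`, `high`, `greenness`. Must sum to 1
#'   (tolerance 1e-9).
#' @param burned_area_km2 Optional absolute burned area; used by
#'   [burned_area_ratio()] when watershed attributes are supplied.
#' @return A `fire_event` list with `bar`, `mix` (burned-area fractions)
#'   and `area_fractions` (watershed-area fractions, `mix * bar`).
#' @export
fire_event <- function(date, bar,
                       severity_mix = c(low = 0.5, moderate = 0.3,
                                        high = 0.2),
                       burned_area_km2 = NA_real_) {
  stop_if(bar < 0 || bar > 1, "bar must be in [0, 1]")
  classes <- c("unburned", "low", "moderate", "high", "greenness")
  stop_if(!all(names(severity_mix) %in% classes),
          "severity_mix names must be among: ",
          paste(classes, collapse = ", "))
  stop_if(any(severity_mix < 0), "severity fractions must be >= 0")
  stop_if(abs(sum(severity_mix) - 1) > 1e-9,
          "severity fractions must sum to 1")
  mix <- setNames(numeric(length(classes)), classes)
  mix[names(severity_mix)] <- severity_mix
  structure(list(date = as.Date(date), bar = bar, mix = mix,
                 area_fractions = mix * bar,
                 burned_area_km2 = burned_area_km2),
            class = "fire_event")
}

#' @rdname fire_event
#' @export
generate_fire_event <- fire_event
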