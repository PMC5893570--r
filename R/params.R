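# Parameter objects for the synthetic watershed generator. Constructors
# validate once so downstream code can assume sane inputs.

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

#' Stochastic weather generator parameters
#'
#' Daily precipitation follows a two-state (wet/dry) Markov occurrence
#' process with a seasonally varying stationary wet-day probability and
#' gamma-distributed wet-day depths. Temperature is an annual sinusoid plus
#' Gaussian noise; daylight hours are a deterministic annual sinusoid whose
#' amplitude stands in for latitude.
#'
#' @param p_wet Stationary wet-day probability per season (recycled to 4:
#'   DJF, MAM, JJA, SON), each in `[0, 1]`.
#' @param wet_depth_mean Mean wet-day precipitation depth (mm), > 0.
#' @param wet_depth_shape Gamma shape for wet-day depths, > 0.
#' @param wet_persistence Lag-1 autocorrelation of the wet/dry chain,
#'   in `[0, 1)`.
#' @param t_mean Annual mean air temperature (degrees C).
#' @param t_amplitude Seasonal temperature half-range (degrees C), >= 0.
#' @param t_noise_sd Daily temperature noise s.d. (degrees C), >= 0.
#' @param daylight_amplitude Half-range of the daylight-hours sinusoid (h);
#'   a latitude proxy (about 3 h near 40 degrees N). Must keep daylight in
#'   `[0, 24]`.
#' @param precip_trend Fractional change in wet-day depth per year
#'   (e.g. -0.015 for a 1.5 %/yr drying trend); default 0.
#' @return A `weather_params` list.
#' @export
weather_params <- function(p_wet = c(0.35, 0.30, 0.20, 0.30),
                           wet_depth_mean = 8,
                           wet_depth_shape = 0.8,
                           wet_persistence = 0.3,
                           t_mean = 8,
                           t_amplitude = 10,
                           t_noise_sd = 3,
                           daylight_amplitude = 3,
                           precip_trend = 0) {
  p_wet <- rep_len(p_wet, 4)
  stop_if(any(p_wet < 0 | p_wet > 1), "p_wet must be in [0, 1]")
  stop_if(wet_depth_mean <= 0, "wet_depth_mean must be > 0")
  stop_if(wet_depth_shape <= 0, "wet_depth_shape must be > 0")
  stop_if(wet_persistence < 0 || wet_persistence >= 1,
          "wet_persistence must be in [0, 1)")
  stop_if(t_amplitude < 0 || t_noise_sd < 0,
          "t_amplitude and t_noise_sd must be >= 0")
  stop_if(daylight_amplitude < 0 || daylight_amplitude > 12,
          "daylight_amplitude must be in [0, 12]")
  structure(list(p_wet = p_wet, wet_depth_mean = wet_depth_mean,
                 wet_depth_shape = wet_depth_shape,
                 wet_persistence = wet_persistence,
                 t_mean = t_mean, t_amplitude = t_amplitude,
                 t_noise_sd = t_noise_sd,
                 daylight_amplitude = daylight_amplitude,
                 precip_trend = precip_trend),
            class = "weather_params")
}

#' Hydrological response parameters
#'
#' Controls how synthetic flow responds to climate: runoff elasticities to
#' annual precipitation and PET (log-log), a degree-day snow module, a
#' linear-reservoir recession for daily routing, and additive daily flow
#' noise.
#'
#' @param eps_p Elasticity of annual flow to annual precipitation
#'   (dimensionless; ~1.5-2.5 for most basins).
#' @param eps_pet Elasticity of annual flow to annual PET (typically <= 0).
#' @param degree_day_factor Snowmelt per degree above threshold
#'   (mm per degree C per day), >= 0.
#' @param snow_threshold Snow/rain partition temperature (degrees C).
#' @param recession Daily linear-reservoir recession coefficient, in (0, 1).
#' @param runoff_coef Long-term runoff ratio Q/P, in (0, 1].
#' @param flow_noise_sd Additive daily flow noise s.d. (mm), >= 0.
#' @return A `hydro_params` list.
#' @export
hydro_params <- function(eps_p = 2.0,
                         eps_pet = -1.0,
                         degree_day_factor = 2.5,
                         snow_threshold = 0,
                         recession = 0.95,
                         runoff_coef = 0.45,
                         flow_noise_sd = 0.2) {
  stop_if(degree_day_factor < 0, "degree_day_factor must be >= 0")
  stop_if(recession <= 0 || recession >= 1, "recession must be in (0, 1)")
  stop_if(runoff_coef <= 0 || runoff_coef > 1, "runoff_coef must be in (0, 1]")
  stop_if(flow_noise_sd < 0, "flow_noise_sd must be >= 0")
  structure(list(eps_p = eps_p, eps_pet = eps_pet,
                 degree_day_factor = degree_day_factor,
                 snow_threshold = snow_threshold, recession = recession,
                 runoff_coef = runoff_coef, flow_noise_sd = flow_noise_sd),
            class = "hydro_params")
}

#' Fire flow-effect parameters
#'
#' The injected fire effect multiplies flow by
#' `1 + coefficient * (moderate + high severity watershed fraction)` for
#' `duration` years after the fire, but only when the burned-area ratio
#' (BAR) reaches `activation_bar`. The default activation of 0.19 reflects
#' the empirical finding that fires burning about 19 % or more of a
#' watershed generally increase river flow.
#'
#' @param activation_bar BAR below which the fire has no flow effect,
#'   in `[0, 1]`.
#' @param coefficient Fractional flow increase per unit moderate+high
#'   severity watershed-area fraction, >= 0.
#' @param duration_years Effect duration (years), >= 1.
#' @param decay `"none"` (constant over the duration) or `"linear"`
#'   (ramps to zero at the end of the duration).
#' @return A `fire_effect_params` list.
#' @export
fire_effect_params <- function(activation_bar = 0.19,
                               coefficient = 1.0,
                               duration_years = 5,
                               decay = c("none", "linear")) {
  decay <- match.arg(decay)
  stop_if(activation_bar < 0 || activation_bar > 1,
          "activation_bar must be in [0, 1]")
  stop_if(coefficient < 0, "coefficient must be >= 0")
  stop_if(duration_years < 1, "duration_years must be >= 1")
  structure(list(activation_bar = activation_bar, coefficient = coefficient,
                 duration_years = duration_years, decay = decay),
            class = "fire_effect_params")
}

#' Static watershed attributes
#'
#' @param area_km2 Drainage area (km2); must exceed 10 km2, the study-design
#'   lower bound for reliably gauged watersheds.
#' @param perimeter_km Watershed perimeter (km), > 0.
#' @param elevation_m Mean elevation (m).
#' @param slope Mean slope (fraction), >= 0.
#' @param landcover Named fractions `forest`, `barren`, `urban`, `other`;
#'   must sum to 1 (tolerance 1e-9).
#' @return A `watershed_attrs` list including the derived Gravelius
#'   compactness `compactness`.
#' @export
watershed_attrs <- function(area_km2, perimeter_km, elevation_m = 500,
                            slope = 0.1,
                            landcover = c(forest = 0.8, barren = 0.05,
                                          urban = 0.05, other = 0.1)) {
  stop_if(area_km2 <= 10, "area_km2 must be > 10 km2")
  stop_if(perimeter_km <= 0, "perimeter_km must be > 0")
  stop_if(slope < 0, "slope must be >= 0")
  need <- c("forest", "barren", "urban", "other")
  stop_if(!all(need %in% names(landcover)),
          "landcover must name forest, barren, urban, other")
  landcover <- landcover[need]
  stop_if(any(landcover < 0) || abs(sum(landcover) - 1) > 1e-9,
          "landcover fractions must be >= 0 and sum to 1")
  structure(list(area_km2 = area_km2, perimeter_km = perimeter_km,
                 elevation_m = elevation_m, slope = slope,
                 landcover = landcover,
                 compactness = gravelius_compactness(perimeter_km, area_km2)),
            class = "watershed_attrs")
}
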