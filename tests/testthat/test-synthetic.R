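# Synthetic watershed generator: weather occurrence/depth process, degree-day
# snowpack, elasticity-driven flow and the injected fire effect.

test_that("degenerate weather settings behave exactly", {
  dry <- generate_daily_weather(weather_params(p_wet = 0), 10, seed = 1)
  expect_true(all(dry$P_mm == 0))

  flat <- generate_daily_weather(weather_params(t_amplitude = 0, t_noise_sd = 0,
                                                t_mean = 4.5), 10, seed = 1)
  expect_true(all(flat$T_C == 4.5))
  expect_true(all(flat$Hr_day >= 0 & flat$Hr_day <= 24))

  expect_error(generate_daily_weather(weather_params(), 9, seed = 1),
               "n_years")
})

test_that("wet-day depth and frequency match the configured process", {
  wp <- weather_params(p_wet = 0.3, wet_depth_mean = 8, wet_depth_shape = 2)
  w <- generate_daily_weather(wp, 30, seed = 42)
  wet <- w$P_mm > 0
  expect_lt(abs(mean(w$P_mm[wet]) - 8) / 8, 0.05)
  # wet-day frequency within 3 binomial sd of 0.3 (Markov persistence
  # inflates the variance; 3 iid-sd is still a generous envelope here)
  se <- sqrt(0.3 * 0.7 / length(wet))
  expect_lt(abs(mean(wet) - 0.3), 6 * se)
})

test_that("snowpack follows the degree-day recursion exactly", {
  n <- 7
  daily <- data.frame(date = seq(as.Date("1990-01-01"), by = "day",
                                 length.out = n),
                      P_mm = c(10, rep(0, n - 1)),
                      T_C = c(-1, rep(1, n - 1)))
  hp <- hydro_params(degree_day_factor = 2, snow_threshold = 0)
  out <- simulate_snowpack(daily, hp)
  expect_equal(out$SWE_mm, c(10, 8, 6, 4, 2, 0, 0))

  warm <- within(daily, T_C <- rep(5, n))
  expect_true(all(simulate_snowpack(warm, hp)$SWE_mm == 0))

  nomelt <- simulate_snowpack(
    transform(daily, T_C = rnorm(n, -3)),
    hydro_params(degree_day_factor = 0))
  expect_true(all(diff(nomelt$SWE_mm) >= 0))
})

test_that("snowpack conserves mass", {
  hp <- hydro_params()
  w <- generate_daily_weather(weather_params(), 12, seed = 3)
  out <- simulate_snowpack(w, hp)
  snow <- sum(out$P_mm[out$T_C < hp$snow_threshold])
  expect_lte(sum(out$melt_mm), snow + 1e-9)
  expect_true(all(out$SWE_mm >= 0))
})

test_that("fire effect is an exact multiplicative counterfactual", {
  hp <- hydro_params()
  w <- simulate_snowpack(generate_daily_weather(weather_params(), 11,
                                                seed = 5), hp)
  # moderate+high watershed fraction = (0.4 + 0.2) * 0.5 = 0.30
  fe <- fire_event("1995-07-01", 0.5,
                   c(low = 0.4, moderate = 0.4, high = 0.2))
  eff <- fire_effect_params(activation_bar = 0.19, coefficient = 1.0)
  d <- simulate_flow(w, hp, fe, eff, seed = 9)
  post <- d$date >= as.Date("1995-07-01") & d$date < as.Date("2000-07-01")
  expect_equal(d$Q_mm[post], d$Q_nofire_mm[post] * 1.30)
  expect_equal(d$Q_mm[!post], d$Q_nofire_mm[!post])
  expect_true(all(d$Q_mm >= 0))

  # below the activation threshold nothing is injected
  small <- fire_event("1995-07-01", 0.10,
                      c(low = 0.4, moderate = 0.4, high = 0.2))
  d2 <- simulate_flow(w, hp, small, eff, seed = 9)
  expect_identical(d2$Q_mm, d2$Q_nofire_mm)

  # zero coefficient: with-fire run equals the counterfactual
  d3 <- simulate_flow(w, hp, fe, fire_effect_params(coefficient = 0),
                      seed = 9)
  expect_identical(d3$Q_mm, d3$Q_nofire_mm)

  expect_error(simulate_flow(w, hp, fire_event("2050-01-01", 0.3), eff),
               "outside")
})

test_that("linear decay ramps the effect to zero over the duration", {
  hp <- hydro_params(flow_noise_sd = 0)
  w <- simulate_snowpack(generate_daily_weather(weather_params(), 11,
                                                seed = 6), hp)
  fe <- fire_event("1995-07-01", 0.5, c(moderate = 0.5, high = 0.5))
  d <- simulate_flow(w, hp, fe,
                     fire_effect_params(coefficient = 0.4, decay = "linear"),
                     seed = 2)
  mult <- ifelse(d$Q_nofire_mm > 0, d$Q_mm / d$Q_nofire_mm, 1)
  on <- which(mult > 1)
  expect_true(all(diff(mult[on]) <= 1e-12))
  expect_lte(max(mult), 1 + 0.4 * 0.5 + 1e-12)
})

test_that("fire event validation and severity arithmetic", {
  ev <- fire_event("2000-08-01", 0.20,
                   c(low = 0.5, moderate = 0.3, high = 0.2))
  expect_equal(unname(ev$area_fractions[c("low", "moderate", "high")]),
               c(0.10, 0.06, 0.04))
  expect_true(all(fire_event("2000-08-01", 0)$area_fractions == 0))
  expect_equal(sum(fire_event("2000-08-01", 0.3,
                              c(low = 1))$area_fractions[c("moderate",
                                                           "high")]), 0)
  expect_error(fire_event("2000-08-01", 0.2, c(low = 0.6, high = 0.6)),
               "sum to 1")
  expect_error(fire_event("2000-08-01", 1.2), "bar")
})

test_that("cohorts are reproducible and carry coherent ground truth", {
  expect_length(generate_cohort(0), 0)
  des <- cohort_design(bar_grid = c(0.05, 0.30))
  a <- generate_cohort(4, des, seed = 7)
  b <- generate_cohort(4, des, seed = 7)
  expect_identical(a, b)
  bars <- vapply(a, function(cs) cs$fire$bar, numeric(1))
  expect_equal(bars, rep(c(0.05, 0.30), 2))
  # below the 19 % activation the true effect is zero by construction
  low <- bars < 0.19
  truth <- vapply(a, function(cs) cs$truth$effect_frac, numeric(1))
  expect_true(all(truth[low] == 0))
  expect_true(all(truth[!low] > 0))
})
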