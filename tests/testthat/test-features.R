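# Derived variables: Hamon PET, Gravelius compactness, BAR, and the 5-year
# pre/post window summaries.

test_that("Hamon PET matches its closed form and is monotone", {
  expect_equal(hamon_pet(20, 0), 0)
  expect_gt(hamon_pet(25, 12), hamon_pet(10, 12))
  expect_gt(hamon_pet(15, 14), hamon_pet(15, 10))
  # independent evaluation of 29.8 * 12 * e_sat(20) / (20 + 273.2) with the
  # Magnus saturation pressure
  oracle <- 29.8 * 12 * 0.6108 * exp(17.27 * 20 / 257.3) / 293.2
  expect_equal(hamon_pet(20, 12), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 2), 2.85)
  expect_error(hamon_pet(-300, 12), "-273.2")
  expect_error(hamon_pet(20, 25), "hr_day")
  # alternative saturation-pressure function is honoured
  expect_equal(hamon_pet(20, 12, esat = function(t) 1),
               29.8 * 12 / 293.2)
})

test_that("Gravelius compactness: circle, square, scale invariance", {
  expect_equal(gravelius_compactness(2 * pi, pi), 1)
  expect_equal(gravelius_compactness(4, 1), 2 / sqrt(pi))
  k <- 3.7
  expect_equal(gravelius_compactness(k * 12, k ^ 2 * 9),
               gravelius_compactness(12, 9))
  expect_error(gravelius_compactness(0, 1), "> 0")
  expect_warning(gravelius_compactness(1, 10), "inconsistent")
})

test_that("burned-area ratio and the plenary/attribution classification", {
  attrs <- watershed_attrs(area_km2 = 100, perimeter_km = 60)
  ev <- fire_event("2000-06-01", bar = 0, burned_area_km2 = 20)
  expect_equal(burned_area_ratio(ev, attrs), 0.20)
  expect_equal(burned_area_ratio(fire_event("2000-06-01", 0), attrs), 0)
  expect_error(burned_area_ratio(
    fire_event("2000-06-01", 0, burned_area_km2 = 150), attrs), "exceeds")
  # membership thresholds: 1 % plenary set, 19 % attribution subset
  expect_true(burned_area_ratio(fire_event("2000-06-01", 0.01), attrs) >= 0.01)
  expect_true(burned_area_ratio(fire_event("2000-06-01", 0.19), attrs) >= 0.19)
})

test_that("watershed attribute validation", {
  expect_error(watershed_attrs(5, 20), "10 km2")
  expect_error(watershed_attrs(100, 60,
                               landcover = c(forest = 0.9, barren = 0.2,
                                             urban = 0, other = 0)),
               "sum to 1")
  a <- watershed_attrs(100, 60)
  expect_equal(a$compactness, 60 / (2 * sqrt(pi * 100)))
})

test_that("window summary aggregates exactly 60 months each side", {
  # 10 years of months, fire at 1995-01; constant P of 60 mm/month
  mon <- make_monthly(rep(60, 120), rep(30, 120))
  ws <- window_summary(mon, as.Date("1995-01-15"))
  expect_equal(unname(ws$pre[["P"]]), 720)
  expect_equal(unname(ws$delta[["P"]]), 0)
  expect_equal(unname(ws$pre[["sigma2_Pm"]]), 0)

  # post window scaled by 1.1 gives exactly +10 %
  mon2 <- make_monthly(c(rep(60, 60), rep(66, 60)),
                       c(rep(30, 60), rep(33, 60)))
  ws2 <- window_summary(mon2, as.Date("1995-01-01"))
  expect_equal(unname(ws2$delta_pct[["P"]]), 10)
  expect_equal(unname(ws2$delta_pct[["Q"]]), 10)

  expect_error(window_summary(mon[1:100, ], as.Date("1995-01-01")),
               "months")
})

test_that("monthly precipitation variance equals its direct recomputation", {
  set.seed(31)
  p <- rgamma(120, 3, 1 / 20)
  mon <- make_monthly(p, p * 0.4)
  ws <- window_summary(mon, as.Date("1995-01-01"))
  expect_equal(unname(ws$pre[["sigma2_Pm"]]), var(p[1:60]))
  expect_equal(unname(ws$post[["sigma2_Pm"]]), var(p[61:120]))
  expect_equal(unname(ws$delta[["sigma2_Pm"]]), var(p[61:120]) - var(p[1:60]))
})

test_that("percent deltas are flagged, not dropped, when pre-mean is zero", {
  mon <- make_monthly(rep(50, 120), rep(20, 120))
  mon$SWE_mm <- c(rep(0, 60), rep(5, 60))
  ws <- window_summary(mon, as.Date("1995-01-01"))
  expect_true("SWE" %in% ws$pct_undefined)
  expect_true(is.na(ws$delta_pct[["SWE"]]))
  expect_equal(unname(ws$delta[["SWE"]]), 5)
})

test_that("window summary is invariant to daily vs monthly granularity", {
  hp <- hydro_params()
  w <- simulate_snowpack(generate_daily_weather(weather_params(), 11,
                                                seed = 8), hp)
  d <- simulate_flow(w, hp, NULL, seed = 4)
  mon <- monthly_series(d)
  fire <- as.Date("1995-07-01")
  ws <- window_summary(mon, fire)
  idx <- mon$date >= as.Date("1990-07-01") & mon$date < fire
  expect_equal(unname(ws$pre[["P"]]),
               sum(d$P_mm[d$date >= as.Date("1990-07-01") &
                          d$date < fire]) / 5)
  expect_equal(unname(ws$pre[["sigma2_Pm"]]), var(mon$P_mm[idx]))
})

test_that("pre-fire annual records split the window into five whole years", {
  hp <- hydro_params()
  w <- simulate_snowpack(generate_daily_weather(weather_params(), 11,
                                                seed = 12), hp)
  d <- simulate_flow(w, hp, NULL, seed = 4)
  mon <- monthly_series(d)
  ann <- prefire_annual(mon, as.Date("1995-07-01"))
  expect_equal(nrow(ann), 5)
  ws <- window_summary(mon, as.Date("1995-07-01"))
  expect_equal(mean(ann$P), unname(ws$pre[["P"]]))
  expect_equal(mean(ann$Q), unname(ws$pre[["Q"]]))
})
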