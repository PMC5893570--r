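# Climate-elasticity models: fitting, BIC selection, significance, and the
# observed/climate/fire decomposition.

make_annual <- function(n = 5, seed = 1, sd = 0,
                        beta = c(P = 0.8, PET = 0, sigma2_Pm = 0, SWE = 0)) {
  set.seed(seed)
  d <- data.frame(P = rnorm(n, 900, 120), PET = rnorm(n, 600, 30),
                  sigma2_Pm = rnorm(n, 1500, 300), SWE = rnorm(n, 40, 15))
  anom <- sweep(as.matrix(d), 2, colMeans(d))
  d$Q <- 400 + as.numeric(anom %*% beta[colnames(anom)]) + rnorm(n, sd = sd)
  d
}

test_that("a noise-free linear relation is identified exactly", {
  ann <- make_annual(sd = 0)
  fits <- fit_cems(ann)
  expect_equal(unname(fits$CEM1$coefficients[["P"]]), 0.8, tolerance = 1e-9)
  expect_lt(fits$CEM1$sse, 1e-18)
  expect_true(all(vapply(fits, `[[`, logical(1), "fittable")))
})

test_that("BIC follows its definition and likelihood bookkeeping", {
  ann <- make_annual(sd = 20)
  fits <- fit_cems(ann)
  for (f in fits) {
    sigma2 <- f$sse / f$n
    loglik <- -f$n / 2 * (log(2 * pi * sigma2) + 1)
    expect_equal(f$loglik, loglik)
    expect_equal(f$bic, -2 * loglik + f$k * log(f$n))
    # ln L = 0 would give BIC = k ln n exactly
    expect_equal(f$bic + 2 * f$loglik, f$k * log(f$n))
  }
  # adding a predictor can only lower SSE but always raises k
  expect_lte(fits$CEM2$sse, fits$CEM1$sse + 1e-12)
  expect_gt(fits$CEM2$k, fits$CEM1$k)
})

test_that("selection prefers the minimum BIC with parsimony tie-breaks", {
  ann <- make_annual(sd = 20)
  fits <- fit_cems(ann)
  best <- select_best_cem(fits)
  bics <- vapply(Filter(function(f) f$fittable, fits), `[[`, numeric(1),
                 "bic")
  expect_equal(best$bic, min(bics))

  # single candidate is returned unconditionally
  expect_identical(select_best_cem(fits["CEM3"])$id, "CEM3")

  # exact BIC tie: fewer parameters win
  tie <- list(
    structure(list(id = "CEM2", fittable = TRUE, bic = 10, k = 3),
              class = "cem_fit"),
    structure(list(id = "CEM1", fittable = TRUE, bic = 10, k = 2),
              class = "cem_fit"))
  names(tie) <- c("CEM2", "CEM1")
  expect_equal(select_best_cem(tie)$id, "CEM1")
  expect_error(select_best_cem(list(structure(list(fittable = FALSE),
                                              class = "cem_fit"))),
               "no fittable")
})

test_that("short records restrict the candidate set", {
  ann <- make_annual(n = 3)
  fits <- fit_cems(ann)
  expect_true(fits$CEM1$fittable)
  expect_false(fits$CEM4$fittable)
  expect_match(fits$CEM4$reason, "insufficient")
  # missing predictor column flags the candidate, not an error
  fits2 <- fit_cems(make_annual()[c("Q", "P", "PET", "sigma2_Pm")])
  expect_false(fits2$CEM4$fittable)
  expect_match(fits2$CEM4$reason, "SWE")
})

test_that("significance testing uses t for CEM1 and F for larger models", {
  ann <- make_annual(n = 8, sd = 5,
                     beta = c(P = 0.8, PET = -0.5, sigma2_Pm = 0, SWE = 0))
  fits <- fit_cems(ann)
  s1 <- cem_significance(fits$CEM1)
  s2 <- cem_significance(fits$CEM2)
  expect_equal(s1$test, "t")
  expect_equal(s2$test, "F")
  expect_true(s1$significant)
  expect_true(s2$significant)

  # n = 3 still admits the CEM1 t-test
  s3 <- cem_significance(fit_cems(make_annual(n = 3, sd = 2))$CEM1)
  expect_equal(s3$test, "t")
  expect_true(is.finite(s3$p_value))
})

test_that("null calibration of the CEM1 t-test", {
  set.seed(44)
  p <- replicate(400, {
    ann <- data.frame(P = rnorm(6, 900, 100), Q = rnorm(6, 400, 50))
    cem_significance(fit_cems(ann)$CEM1)$p_value
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
})

test_that("climate prediction is the coefficient-delta dot product", {
  ann <- make_annual(sd = 0)
  f1 <- fit_cems(ann)$CEM1
  expect_equal(predict_dq_clim(f1, c(P = 0)), 0)
  expect_equal(predict_dq_clim(f1, c(P = 50)), 0.8 * 50, tolerance = 1e-9)

  f4 <- fit_cems(make_annual(sd = 0,
                             beta = c(P = 0.6, PET = 0, sigma2_Pm = 0,
                                      SWE = 1.5)))$CEM4
  deltas <- c(P = -30, SWE = 12)
  expect_equal(predict_dq_clim(f4, deltas),
               sum(f4$coefficients * deltas[c("P", "SWE")]))
  expect_error(predict_dq_clim(f4, c(P = 1)), "SWE")
})

test_that("the attribution identity holds exactly and flags edge cases", {
  a <- attribute_disturbance(10, -5, q_pre = 200, bar = 0.25)
  expect_identical(a$dq_dist, 15)
  expect_equal(a$dq_dist_pct, 100 * 15 / 200)
  expect_true(a$eligible)

  b <- attribute_disturbance(-8, -8, q_pre = 100, bar = 0.05)
  expect_identical(b$dq_dist, 0)
  expect_false(b$eligible)

  c0 <- attribute_disturbance(4, 1, q_pre = 0)
  expect_true(c0$pct_suppressed)
  expect_true(is.na(c0$dq_dist_pct))
  expect_identical(c0$dq_dist, 3)

  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(3) * 10 ^ sample(-2:3, 3, TRUE)
    at <- attribute_disturbance(v[1], v[2], abs(v[3]) + 1)
    expect_identical(at$dq_dist, v[1] - v[2])
  }
})

test_that("a drying climate can mask a positive fire effect", {
  des <- cohort_design(weather = weather_params(precip_trend = -0.04),
                       precip_trend_range = c(0, 0),
                       effect = fire_effect_params(coefficient = 1.0),
                       bar_grid = 0.30,
                       severity_mix = c(low = 0.2, moderate = 0.4,
                                        high = 0.4))
  cs <- generate_cohort(1, des, seed = 2)[[1]]
  ws <- window_summary(cs$monthly, cs$fire$date)
  best <- select_best_cem(fit_cems(prefire_annual(cs$monthly, cs$fire$date)))
  att <- attribute_disturbance(ws$delta[["Q"]], predict_dq_clim(best, ws),
                               ws$pre[["Q"]], bar = cs$fire$bar)
  expect_gt(cs$truth$effect_pct_of_pre, 0)
  expect_lt(att$dq_obs_pct, 0)          # observed flow declined ...
  expect_gt(att$dq_dist_pct, 0)         # ... yet the fire part is positive
  expect_gt(att$dq_dist, att$dq_obs)    # climate correction is upward
})
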