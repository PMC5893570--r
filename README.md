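# fireflow

Detection and attribution of wildland fire impacts on river flow.

After a fire burns part of a gauged watershed, did river flow actually
change — and if it did, how much of the change was the fire and how much
was the climate? `fireflow` answers this with a four-step statistical
framework for monthly flow (`Q`), precipitation (`P`), potential
evapotranspiration (PET, Hamon's method), snow-water equivalent (SWE) and
fire records, comparing the five years before and after each fire:

1. **Change-point test on monthly flow.** The Lepage statistic
   `L = U*² + M²` combines a standardized Mann–Whitney rank component
   (location shifts) with a standardized Mood component (scale shifts);
   `L` is maximized over candidate change points and compared with a
   permutation-calibrated critical value `h_t`. The no-change null is
   rejected only when the change localizes within a year after the fire.
2. **Structural break in the double-mass curve.** Cumulative `Q` against
   cumulative `P` is piecewise-linear if the water-yield ratio shifts at
   the fire date; Chow's test
   `F = [(SSE₀ − SSE₁ − SSE₂)/K] / [(SSE₁+SSE₂)/(n−2K)]` decides.
3. **Boosted relative influence with random probes.** Gradient-boosted
   regression of the 5-year flow change `dQ` on ~30 fire, geometry,
   climate and land-cover variables; a variable is influential only if it
   beats two probe variables that cannot carry signal. Refitting on
   subsets with burned-area ratio `BAR ≥ {1, 10, 15, …, 25} %` scans for
   the critical threshold `BAR_t` above which burn severity affects flow.
4. **Climate-elasticity attribution.** Four candidate elasticity models
   (`dP`; `dP, dPET`; `dP, dσ²_Pm`; `dP, dSWE`) are fitted to the five
   pre-fire years in anomaly form, selected by BIC
   (`−2 ln L_k + k ln n`), significance-tested, and used to predict the
   climate-expected flow change. The fire-attributed part is the
   remainder: `ΔQ_dist = ΔQ_obs − ΔQ_clim`.

A seeded synthetic watershed generator (stochastic seasonal weather,
degree-day snowpack, elasticity-driven flow, and a threshold-gated
multiplicative fire effect with an exact no-fire counterfactual) provides
ground truth, so every step of the pipeline is testable end to end. See
`vignettes/fireflow-methods.Rmd` for the full model description, parameter
choices and limitations.

## Worked example

Generate a 40-watershed cohort and run the full pipeline, pinning
`BAR_t` at the conventional 19 %:

```r
library(fireflow)
cohort <- generate_cohort(40, cohort_design(), seed = 42)
result <- run_pipeline(cohort, pipeline_config(bar_t = 0.19, seed = 42))
result
#> <pipeline_result> 40 watersheds (0 errors)
#>   flow-disturbed 4 | yield-disturbed 39 | CEM-significant 36 | attributed 6
#>   BAR_t = 19%; attributed medians: dQ_obs +45.6%, dQ_clim +14.8%, dQ_dist +35.2%
```

Of 40 burned watersheds, 39 show a yield-ratio breakpoint at the fire
date, 36 support a significant elasticity model, and 6 pass all
attribution gates (`BAR ≥ 19 %`, breakpoint, significant model); among
those, the median observed flow change of +45.6 % decomposes into +14.8 %
expected from climate and +35.2 % attributed to fire.

Walking one attributed watershed through the steps:

```r
cs <- cohort[[25]]
cs
#> <synthetic_case ws025> BAR 26.5%, mod+high 18.2% of watershed, injected effect +18.2% of flow

test_flow_disturbance(cs$monthly, cs$fire$date, n_perm = 999, seed = 1)
#> <changepoint_result> L_max = 39.606, h_t = 11.030 (alpha = 0.05, 999 perms)
#>   change detected at split 39; fire-linked: FALSE

test_yield_disturbance(cs$monthly, cs$fire$date)
#> <chow_result> F(2, 116) = 231.686, p = 3.069e-41: break detected at index 60

ws   <- window_summary(cs$monthly, cs$fire$date)
best <- select_best_cem(fit_cems(prefire_annual(cs$monthly, cs$fire$date)))
best
#> <cem_fit CEM3> n = 5, BIC = 48.13; coefficients: P = 0.714, sigma2_Pm = 0.075

attribute_disturbance(ws$delta[["Q"]], predict_dq_clim(best, ws),
                      ws$pre[["Q"]], bar = cs$fire$bar)
#> <attribution> dQ_obs +211.3 mm (+56.5%) = dQ_clim +119.7 mm (+32.0%) + dQ_dist +91.6 mm (+24.5%)
#>   BAR 26.5% >= BAR_t 19.0%: fire-attribution eligible
```

The change-point scan found its maximum at a wet-year transition long
before the fire (so step 1 retains its null — the change is not
fire-linked), but the double-mass curve breaks sharply at the fire date,
and the elasticity model splits the observed +56.5 % flow increase into
+32.0 % from a wetter post-fire climate and +24.5 % attributed to fire —
close to this watershed's injected ground-truth effect of +18.2 % of flow
(+24.1 % of pre-fire flow after climate rescaling of the counterfactual).
Per-watershed attributions carry noise from five-point elasticity fits;
cohort medians are considerably more stable.

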