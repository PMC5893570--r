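Package: fireflow
Title: Detection and Attribution of Wildland Fire Impacts on River Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A stepwise statistical framework for deciding whether a wildland
    fire disturbed river flow in a gauged watershed and, if so, how much of
    the observed flow change is attributable to the fire rather than to
    climate variability. Implements nonparametric change-point detection on
    monthly flow with the Lepage statistic (Mann-Whitney location plus Mood
    scale components) and a permutation-calibrated critical value; structural
    break detection in the double-mass curve of cumulative flow against
    cumulative precipitation with Chow's F-test; gradient-boosted relative
    influence screening with random probe variables and a burned-area-ratio
    threshold scan; and climate-elasticity models selected by BIC that
    decompose the 5-year post-fire flow change into climate-expected and
    fire-attributed parts. Ships a seeded synthetic watershed generator
    (stochastic weather, degree-day snowpack, elasticity-driven flow with an
    injected fire effect) so the whole pipeline is testable with known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
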