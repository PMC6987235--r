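Package: droughtring
Title: Tree-Ring Growth Resilience to Drought and Subsequent Mortality Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline linking tree growth resilience to past drought
    events with subsequent drought-induced mortality. Reads and writes Tucson
    decadal ring-width files, standardises individual series with a cubic
    smoothing spline (50% frequency response at 67% of series length),
    prewhitens with an AR model and builds Tukey-biweight residual site
    chronologies; computes multiscale SPEI drought indices from monthly
    precipitation and potential evapotranspiration via log-logistic
    probability-weighted-moment standardisation; selects each site's best SPEI
    window by AIC over 120 candidates and detects a single extreme drought
    event per site; computes Lloret resistance, recovery and resilience
    indices on ring width and basal area increment; and contrasts now-dead
    against surviving trees with linear mixed models (nested random effects,
    AIC reduction, standardised coefficients, marginal and conditional R2,
    back-transformed adjusted means). A seeded synthetic-data generator with
    known ground truth stands in for the pancontinental tree-ring database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    lme4,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
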