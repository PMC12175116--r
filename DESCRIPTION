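Package: seatrend
Title: Seascape-Wide Synthesis of Population Trends in Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies long-term population monitoring series into nine
    trend types via generalized linear model selection (Gaussian on
    log-transformed abundance, Poisson, and negative binomial; linear and
    quadratic in year) with residual diagnostics and a Mitchell-Olds and
    Shaw test for interior extrema; summarises trends through year-weighted
    vote counts; pools linear slopes in multilevel random-effects
    meta-analyses (station as random effect, REML) to identify winner and
    loser taxa at several taxonomic ranks; and models yearly trend-direction
    states with mixed binomial and multinomial logit models with cluster
    bootstrap confidence bands. Includes a synthetic monitoring-data
    generator with known ground truth for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lmtest,
    metafor,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nnet,
    vegan,
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
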