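Package: sporoscale
Title: Spatio-Temporal Scales of Variation in Fungal Sporocarp Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-year epigeous sporocarp (mushroom)
    surveys along environmental gradients. Aggregates weekly collection
    records into plot-by-year biomass, species richness and Pielou evenness
    tables; partitions variance across plot, locality and year scales by
    restricted maximum likelihood with case-bootstrap confidence intervals;
    fits penalized B-spline mixed models with nested random intercepts,
    first-order autoregressive residuals and late-summer/early-autumn
    climate covariates for Gaussian and Poisson responses; detects
    significant fruiting pulses from finite-difference derivatives of the
    fitted trends; and regresses per-plot between-year variances on
    elevation. Includes a synthetic survey generator with known ground
    truth emulating a nested 19-plot, 4-locality, 8-year weekly sampling
    design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    splines,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    mgcv,
    nlme,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
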