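Package: pdbia
Title: Budget-Impact Model for Wearable Parkinson's Monitoring
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic budget-impact model for introducing a wearable
    motor-fluctuation monitoring device into national health systems caring
    for Parkinson's disease patients.  Maps Hoehn & Yahr staging onto a
    three-stage (mild/moderate/advanced) model, propagates an
    underdiagnosis -> detection -> adoption cascade, amortises device cost
    per patient-year, and evaluates per-patient and national annual savings
    from stage reclassification under two detection scenarios.  Includes
    one-way sensitivity sweeps, tornado ranking, Monte-Carlo uncertainty
    propagation, break-even device pricing, and a synthetic country-portfolio
    generator for property testing.  Ships the published five-country
    European parameter set as a bundled portfolio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
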