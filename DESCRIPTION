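Package: epimapr
Title: Epicardial Electrotype Mapping and Arrhythmic Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing and analysis pipeline for non-invasive epicardial
    unipolar electrograms on a triangulated heart surface: baseline filtering,
    template matching and signal averaging of multi-beat strips, rule-based
    QRS/T delineation with interpretability rejection, activation and
    repolarization markers (Wyatt method), whole-heart summary metrics (mean,
    central-95% dispersion, 5-mm spatial gradients), qualitative map-pattern
    detectors, non-parametric group statistics, and a Newton-fitted logistic
    risk model with backward stepwise selection and repeated stratified
    k-fold cross-validation. Includes a seeded synthetic-cohort generator
    that realizes configurable activation/repolarization fields as raw
    electrogram strips so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
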