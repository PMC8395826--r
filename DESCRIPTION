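Package: trecscreen
Title: Simulation and Evaluation of TREC-Based Newborn Screening for SCID
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying dried-blood-spot newborn screening for severe
    combined immunodeficiency (SCID) based on T cell receptor excision circle
    (TREC) quantification. Provides a synthetic screened-cohort generator
    calibrated to published gestational-age-stratified TREC/KREC reference
    distributions, a forward model of 96-well qPCR plates with standard-curve
    quantification and plate acceptance rules, the epoch-dependent screening
    decision algorithm (reanalysis band, replicate consensus, referral and
    inconclusive verdicts), and clinical-performance evaluation: Wilson score
    intervals for proportions, exact Poisson incidence intervals, stratified
    referral rates, and post hoc referral cut-off sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
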