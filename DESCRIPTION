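Package: mmgrowth
Title: Modified Michaelis-Menten Modelling of Infant Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a modified Michaelis-Menten saturating curve to individual
    children's longitudinal weight and height measurements from birth to 36
    months by Gauss-Newton nonlinear least squares, with divergence
    detection for linear growers. Includes protocol cleaning rules and the
    12 recommended well-baby visit windows, a visit-dropping imputation
    study, a seeded single-point holdout comparison against common
    interpolators, last-value prediction of year-3 growth, and a
    synthetic-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
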