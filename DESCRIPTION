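Package: swimnet
Title: Seasonal Change Networks for Age-Group Swimmers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses a longitudinal age-group swimming season from paired
    (before/after) measurement sessions: stroke kinematics (speed, stroke
    rate, stroke length, stroke index) from timed 25-m trials, somatic
    maturity offset from anthropometrics (Mirwald equations), paired
    effect-size statistics (Hedges' g with Hopkins magnitude bands), and a
    regularized partial-correlation network over percent-change scores
    estimated by the graphical lasso with extended-BIC model selection.
    Includes weighted-network centrality measures (betweenness, closeness,
    strength) standardized to z-scores, and a synthetic-cohort generator so
    every stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
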