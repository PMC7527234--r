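Package: embryorank
Title: Embryo Cohort Ranking and Selection with Genetic-Algorithm Scoring
    Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for converting a blastocyst-quality classifier's
    five-class probability vectors into a single transfer score via a
    genetic-algorithm-optimised linear weight vector, ranking patient
    embryo cohorts for single and double embryo transfer (SET/DET),
    scoring implantation potential, and evaluating selections with exact
    binomial confidence intervals, ROC/AUC analysis, rater-comparison
    tests and implantation-score bins.  A seeded synthetic-cohort
    generator emulates the statistical structure of clinical embryo
    cohorts so the whole pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
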