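Package: lungturnover
Title: Temporal Turnover and Assembly Processes in Longitudinal Lung
    Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of temporal turnover in longitudinal airway microbiota
    time series. Partitions each patient's taxa into chronic and intermittent
    colonizers by a persistence criterion (modified Leeds criteria), fits
    persistence-abundance relationships, constructs species-time relationships
    by the moving-window method with power-law turnover exponents, attributes
    community assembly to homogenizing dispersal, drift, or dispersal
    limitation via a Monte-Carlo Raup-Crick null model, and relates the
    inferred processes to lung function with nonparametric cohort statistics.
    Includes a synthetic-cohort generator with the statistical structure the
    analysis assumes, so the whole pipeline is testable without sequencing
    data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
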