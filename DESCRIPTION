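Package: airedna
Title: Long-Term Airborne Environmental DNA Biodiversity Time Series Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing multi-decadal biodiversity dynamics from
    weekly airborne environmental DNA (eDNA) read-count tables. Implements
    compositional data handling (Bayesian-multiplicative zero replacement,
    CLR/ILR/pivot log-ratio transforms, variation matrices), gradient-boosted
    filtering of spurious taxon detections from read-classification summary
    statistics, removal of read-length and filter-batch artifacts, temporal
    assemblage clustering, Renyi/Hill alpha-beta-gamma diversity partitioning
    with era contrasts, Bayesian structural state-space trend models with
    leave-future-out model comparison, cross-validation against point-transect
    survey indices, and back-trajectory catchment summaries with simplified
    quantitative transport bias analysis. A synthetic-data generator with
    retrievable ground truth emulates the statistical structure of the weekly
    aerosol sampling design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ape,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
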