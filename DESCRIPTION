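Package: microstasis
Title: Longitudinal Microbiome Stability, Convergence and Source-Tracking Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for dense longitudinal 16S microbiome cohorts
    sampled across environmental transitions (for example crews entering and
    leaving a closed habitat). Implements reference-community normalization of
    compositional time series via Jensen-Shannon-weighted medians, stationarity
    assessment with the autocorrelation function, Mann-Kendall trend tests,
    weighted UniFrac beta diversity with grouped Kruskal-Wallis comparisons,
    PCA/MANOVA group separation on Mahalanobis distances, expectation-
    maximization microbial source tracking with an unknown component, and
    Spearman co-occurrence networks between abundant genera and host markers.
    Ships a seeded synthetic cohort generator so every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
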