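Package: sandassembly
Title: Community Assembly Analysis for Coastal Sand Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the ecological processes behind microbial community
    assembly in intertidal and supratidal beach sands from amplicon count
    tables.  Provides Levins' niche breadth with fixed-fixed permutation
    nulls for habitat generalist/specialist classification, Dufrene-Legendre
    indicator value (IndVal) analysis, abundance-based beta-null deviations,
    Sloan neutral community model fitting with taxon partitioning, and
    distance-based multivariate statistics (PERMANOVA, ANOSIM, PCNM spatial
    eigenvectors, db-RDA variation partitioning with forward selection).
    A synthetic metacommunity generator with known assembly regimes
    (neutral Moran dynamics, Gaussian niche filtering, or both) provides
    ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml,
    permute,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
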