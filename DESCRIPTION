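Package: clonetail
Title: Spliced Bulk-Tail Modeling of Immune Repertoire Clone Size
    Distributions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Model-based analysis of T cell receptor (TCR) repertoire clone
    size distributions. Fits a discrete spliced threshold model -- a
    right-truncated discrete Gamma bulk below a threshold and a discrete
    generalized Pareto (GPD) tail above it -- with data-driven threshold
    selection by profile likelihood over a grid of candidate thresholds.
    Includes a type-I Pareto comparator fitted by Kolmogorov-Smirnov
    minimization, ecological diversity statistics (richness, Shannon
    entropy, clonality, and the proportion of highly stimulated clones),
    Jensen-Shannon-distance comparative analysis across samples with Ward
    hierarchical clustering and non-metric multidimensional scaling, and a
    cohort simulator with exact read downsampling for sequencing-depth
    robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    ape,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
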