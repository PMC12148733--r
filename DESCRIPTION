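Package: tumevo
Title: Multi-Region Tumor Evolution Analysis from Read-Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intratumoral heterogeneity from multi-region
    somatic mutation tables with per-region read counts. Converts read counts to
    variant allele frequencies and cancer cell fractions, clusters mutations with
    a binomial mixture model selected by BIC, classifies mutations as public,
    shared or private across regions, builds rooted neighbor-joining phylogenies
    with mutation-count branch lengths and tree-shape labels, profiles per-sample
    VAF distributions (Gaussian mixture peaks, neutral-tail detection, MATH
    score, TMB/MSI threshold rules), and compares cohorts with Fisher, Pearson
    chi-squared and Mann-Whitney statistics. Includes a clonal-evolution
    simulator generating multi-region read-count data under continuous-selection
    and selection-then-neutral regimes with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
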