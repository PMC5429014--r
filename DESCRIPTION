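Package: c4scan
Title: Genome-Wide Branch-Model Selection Scans over Syntenic Ortholog
    Groups in Grasses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for cross-species selection scans on
    pan-grass syntenic ortholog groups: homeolog-aware ortholog grouping,
    codon-aware progressive alignment with conserved-block trimming,
    gene-tree congruence filtering by quartet distance, branch-model
    dN/dS likelihood-ratio tests under a catalogue of phylogenetic
    conditions with C4 foreground branches, and FDR-based candidate
    merging. Includes a forward codon simulator with branch-specific
    omega for cohort-level calibration and power experiments. Likelihood
    computations (Goldman-Yang codon model, GTR+Gamma+I, Felsenstein
    pruning) are implemented in C++.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
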