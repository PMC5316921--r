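Package: sweepscan
Title: Selection Scans for Diverged Crop Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recent positive and divergent selection between a reference
    (landrace-like) and a test (weedy-like) population from multi-sample VCF
    genotypes. Implements five selection statistics (windowed nucleotide
    diversity and reduction of diversity, Weir-Cockerham FST, iHS, XP-EHH and a
    simplified XP-CLR composite-likelihood model), empirical top-quantile
    outlier calling, gene mapping with multi-metric candidate intersection,
    linkage-disequilibrium decay and genotype PCA summaries, k-means
    co-expression clustering with tissue-specificity rules, and a built-in
    two-population Wright-Fisher forward simulator with planted hard sweeps for
    calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    vcfR,
    ape,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
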