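Package: sdscan
Title: Singleton-Density Selection Scans and Enrichment Tests for Recent
    Positive Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects very recent positive selection from phased
    whole-genome sequencing panels using a singleton-density score: per
    individual, distances from each common variant to the nearest
    flanking singletons are contrasted between haplotypes carrying the
    derived versus the ancestral allele, standardized within derived
    allele frequency bins, and meta-analyzed across sequencing datasets
    with sample-size weights.  Includes the accompanying enrichment
    procedures (derived allele frequency heterogeneity across
    subpopulations against a frequency-matched empirical null, circular
    rotation permutation of introgression tract sets along concatenated
    chromosomes, and a chi-square sum test for trait-associated variant
    sets with LD-proxy expansion), plus a seeded synthetic-data generator
    that emulates the statistical structure of such studies so the whole
    pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
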