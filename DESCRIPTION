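Package: poolstrat
Title: Stratification Analysis of Pool-Sequenced Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing genetic stratification among closed breeding
    colonies from pooled whole-genome sequencing. Estimates allele frequencies
    from pooled read counts, computes pairwise fixation indices (FST) and
    Reynolds genetic distances, tests allele-frequency differences between
    pools with a pooled-variance F-test, runs principal component analysis
    with a missing-data-adjusted covariance, builds UPGMA trees with
    locus-resampling support, summarises heterozygosity, oppositely fixed
    loci and private polymorphisms, profiles functional-class enrichment
    across differentiation strata, and selects representative pool candidates
    from a pedigree-derived relationship matrix. A Wright-Fisher drift
    simulator generates pool-seq data with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
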