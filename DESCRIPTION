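Package: methclime
Title: Genetic and Environmental Control of DNA Methylation in Structured
    Plant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for dissecting natural variation in
    plant DNA methylomes across growth environments. Covers bisulfite
    cytosine-report quantification (site levels, conversion efficiency,
    context averages, sliding windows, gene-body-methylation calling),
    Fisher-test differential methylation with transposon-family permutation
    enrichment, kinship-corrected mixed-model GWAS with stepwise cofactors
    and an F2 Haley-Knott scan, a two-environment matrix-normal variance
    decomposition into cis, trans, major-locus and environment-interaction
    fractions, and population-level tests of local adaptation (Hudson Fst,
    Haseman-Elston Qst, climate correlations, SNP-set permutation
    enrichment). A synthetic-data generator with known truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
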