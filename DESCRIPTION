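Package: teislandr
Title: Transposable-Element Island Detection and Intragenomic Divergence
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transposable-element (TE) islands from sliding-window
    annotation density, partitions genome scaffolds into islands and
    low-density regions (LDRs), and quantifies how the two compartments
    diverge between lineages: pooled-coverage ratio deviations, SNV region
    summaries, collapsed-duplication classification of heterozygous calls,
    coding-effect annotation with dN/(dN+dS), repeat superfamily and term
    enrichment, gene-body CpG observed/expected ratios, and size-factor
    normalised expression comparisons. Includes a synthetic-genome
    generator with planted ground truth for recovery testing, and a
    single-config pipeline that emits a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
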