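Package: panelaudit
Title: Tumor-Normal Versus Tumor-Only Gene-Panel Variant Audit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the cost of tumor-only sequencing on targeted cancer
    gene panels. Classifies single nucleotide variants as germline or somatic
    from matched tumor/normal read evidence, simulates tumor-only variant
    filtering against population databases (database membership and allele
    frequency thresholds), and tallies the resulting false positives (germline
    variants reported as somatic) and false negatives (somatic variants
    removed) at cohort, gene and patient scope, including the impact on
    drug-targetable genes. Assesses whether DNA variants are expressed in
    tumor RNA from allele-specific read counts, and ships a paired-sample
    cohort simulator with ground truth so every stage is testable without
    external data. All user-facing functions take and return tidy data frames.
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
    S4Vectors,
    stats,
    SummarizedExperiment,
    stringr,
    tibble,
    tidyr,
    utils,
    VariantAnnotation,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
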