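Package: nitrolnc
Title: Low-Nitrogen-Responsive lncRNAs, ceRNA Networks and GWAS Integration in Maize
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for dissecting long noncoding RNA
    (lncRNA) responses to nitrogen deficiency in maize seedlings. Covers the
    five-step filter cascade that turns assembled transcripts into lncRNA,
    TUCP and rejected classes (with lincRNA/antisense classification),
    negative-binomial differential expression between high- and low-nitrogen
    treatments, cis/trans target assignment, plant miRNA target-site penalty
    scanning and competing-endogenous-RNA (ceRNA) triplet networks, seedling
    phenotype statistics (broad-sense heritability, low-nitrogen tolerance
    index), mixed-linear-model genome-wide association with genomic kinship,
    linkage-disequilibrium decay candidate windows, and the intersection of
    association candidates with expression calls. A seed-reproducible
    synthetic-data generator plants ground truth at every stage for
    validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
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
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
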