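Package: cnvrscan
Title: Segment-Based Case/Control Association Scanning for SNP-Array CNVs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for copy-number-variant (CNV) case/control
    association from SNP-array data: ingestion of PennCNV-style call lists
    and probe maps, per-sample quality control (call rate, LRR noise,
    GC waviness, CNV burden, identity-by-descent relatedness, genotype PCA),
    a simplified LRR/BAF hidden Markov CNV caller, a per-probe Fisher exact
    carrier scan collapsed into copy-number-variable regions (CNVRs) with an
    experiment-wide Bonferroni threshold, gene/exon/cytoband annotation and
    cohort profiling, plus a fully seeded synthetic-cohort generator so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
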