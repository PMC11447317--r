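Package: plastocub
Title: Codon Usage Bias Analysis for Plastid Protein-Coding Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for codon usage bias (CUB) analysis of plastome
    coding sequences: CDS extraction from GenBank flat files or FASTA, quality
    filtering, per-gene codon usage indices (RSCU, Wright's effective number of
    codons, positional GC content, synonymous third-base composition),
    mutation-versus-selection diagnostics (neutrality plot, ENC-plot with the
    mutation-only expectation curve, ENC frequency ratio, PR2 bias plot),
    Spearman correlation of indices, optimal-codon determination from
    high-frequency and high-expression codon sets, and RSCU-based hierarchical
    clustering of species. Includes a seeded generator of plastome-like
    synthetic CDS collections with known ground truth so every stage is
    testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
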