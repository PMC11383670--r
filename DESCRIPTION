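Package: redecap
Title: Redundant mRNA Decapping Activator Analysis from Multi-Omics Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of functional redundancy among mRNA
    decapping activators (Scd6, Edc3, Dhh1, Pat1) in budding yeast from
    multi-omics count data. Generates ground-truthed negative-binomial count
    tables for RNA-seq, ribosome profiling, CAGE, 5'P degradome and Pol II
    ChIP assays under a steady-state synthesis/decay model; implements
    within-sample and spike-in normalization (median-of-ratios, TPM, ERCC
    and heterologous-chromatin scaling), negative-binomial Wald tests for
    differential mRNA and ribosome-footprint abundance, a translational
    efficiency shift test, Benjamini-Hochberg FDR control, threshold-based
    regulated-set calling, three-set Venn arithmetic with hypergeometric
    overlap enrichment, epistasis-sector classification of double-mutant
    regulation, environmental stress response filtering and signature
    scoring, capped-to-total (C/T) ratios, the codon protection index, and
    a transcription-versus-decay decomposition of spike-in normalized fold
    changes corrected for per-cell ribosome content.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), optparse, withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
VignetteBuilder: knitr
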