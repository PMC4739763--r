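Package: coenosplice
Title: Junction-Library Quantification of Alternative Splicing with
    lincRNA Discovery, Cross-Species Expression Clustering and Secretome
    Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for junction-read based quantification of intron
    retention (percent intron retention, PIR) and exon skipping (percent
    spliced in, PSI) in compact genomes, built around an explicit
    exon-exon / exon-intron junction reference library with per-junction
    mappability correction. Includes a synthetic-data generator (toy
    genome, GT-AG gene models, stranded reads and predictor evidence
    tables with known truth), de novo splice-site and microexon
    discovery, differential-splicing calling, a long intergenic
    non-coding RNA (lincRNA) discovery filter cascade with orientation
    and enrichment statistics, cross-species ortholog-expression
    clustering (Spearman distances, hierarchical and neighbor-joining
    trees with bootstrap, PCA loadings, gene-module co-regulation), and
    an in-silico secretome triage cascade over signal-peptide,
    transmembrane, targeting and GPI predictor tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    limma,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
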