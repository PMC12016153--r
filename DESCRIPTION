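Package: methylscope
Title: Bacterial Methylome Analysis from Modified-Base Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of bacterial DNA methylation (6mA, 5mC, 4mC) from
    per-position modified-base pileups in the 18-column bedMethyl dialect.
    Computes the Fraction Modified and Percent Modified statistics, calls
    per-position methylation, scans and summarizes IUPAC degenerate
    methylation motifs with full both-strand bookkeeping, discovers motifs
    de novo from methylated-base contexts, quantifies methylation density
    over genes, windows and 40-base promoter/start/end regulatory regions,
    and detects strand-specific, methylation-induced basecalling
    ambiguities (IUPAC R/Y) from strand-split base counts. Includes a
    synthetic-data generator that emits genomes with planted motifs,
    annotations, pileups and strand counts with ground-truth manifests, so
    the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
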