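Package: raslsplice
Title: Comparative Alternative-Splicing Analysis of RASL-seq Junction Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative alternative-splicing analysis of
    RASL-seq style junction-probe count data: detection filtering,
    isoform-ratio differential-splicing calls with per-event-type
    tallies, splice-site strength scoring from fixed donor/acceptor
    windows, exon/intron architecture statistics with group
    comparisons, k-mer motif enrichment on flanking introns,
    AS-NMD classification of exon-skipped isoforms by the
    premature-termination-codon junction rule, and PSI computation
    from transcript abundances. Includes a deterministic
    synthetic-data generator (genome, annotation, probe panel,
    replicate counts with planted effects) so every stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
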