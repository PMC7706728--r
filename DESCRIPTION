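Package: promarch
Title: Promoter Architecture from Chromatin Accessibility, Nucleosome
    Occupancy and Dinucleotide Periodicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Characterizes promoter chromatin architecture from paired-end
    ATAC-seq data and genome sequence. Builds fragment density V-plots over
    anchor sets and scores flanking-nucleosome enrichment; detects 10-bp WW
    dinucleotide periodicity in sequence sets by power spectral density of
    pairwise dinucleotide distances and emits running periodicity tracks;
    calls +1/-1 nucleosomes from occupancy probability tracks relative to
    divergent transcription start site modes and derives promoter metrics
    (TSS-to-nucleosome-edge distance, TSS mode separation, nucleosome
    depleted region width); phases nucleosomal dinucleotide matrices by
    k-means and lagged cross-correlation; and classifies accessible sites
    and genes into tissue-specificity classes from signal matrices and
    pairwise differential tables. Includes seeded generators for every
    input format so the full toolkit is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    jsonlite,
    optparse,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
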