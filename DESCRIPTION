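Package: dpcrepair
Title: Quantification of Transcription-Coupled DNA-Protein Crosslink Repair from Binned Sequencing Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying transcription-coupled repair of
    DNA-protein crosslinks (DPCs) from genome-binned sequencing counts.
    Partitions a genome into fixed-width bins, aggregates aligned fragment
    intervals with featureCounts-style fractional overlap counting, combines
    replicates on a common library scale, applies an IQR outlier filter and a
    DNA TPM floor with cross-dataset mask propagation, rescales the 0 h sample
    to the 4 h level using zero-transcription reference bins, and computes
    per-bin repair percentages with expression-stratified summaries and
    gene-level repair profiles. Also implements FRAP immobile-fraction
    estimation with configurable recovery windows and qPCR relative
    quantification (2^-ddCt and 2^-dCt chains). A synthetic-data generator
    with known ground truth (genomes, nascent-RNA expression tracks, DPC bin
    counts, FRAP traces, Ct tables) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
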