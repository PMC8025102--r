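Package: emsbias
Title: Genome-Wide Analysis of EMS Mutagenesis Bias from Multi-Bulk Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to identify ethyl methanesulfonate (EMS)-induced single
    nucleotide polymorphisms from multi-bulk bulked-segregant resequencing
    variant tables, and to characterise the genomic biases of EMS
    mutagenesis: mutation spectra and sequence-context (k-mer) preferences,
    sliding-window hotspot and coldspot detection with chi-square density
    thresholds, CpG-island calling, and overlay statistics against DNase I
    hypersensitive sites, transposable-element annotation, gene expression,
    and epigenetic signal tracks. Includes a synthetic-data generator that
    emulates the statistical structure of a pooled-F2 mutagenesis screen
    (context-biased mutation rates, shared natural variants, sequencing
    error, residual heterozygous fragments, and chromatin-correlated
    tracks) with a ground-truth manifest for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
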