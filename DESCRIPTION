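Package: deaseq
Title: Deaminase-Assisted Profiling of 5-Glyceryl-Methylcytosine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for base-resolution profiling of
    5-glyceryl-methylcytosine (5gmC) with deaminase-assisted sequencing
    (DEA-seq), TET-coupled bisulfite sequencing and whole-genome bisulfite
    sequencing. Provides spike-in conversion-rate estimation, threshold-based
    5gmC site calling with knockout-control subtraction and gradient threshold
    selection, deconvolution of 5mC from WGBS signal, genomic-landscape
    annotation (cytosine context, functional regions, transposable elements,
    histone marks) and modification-expression association analyses, together
    with a synthetic-chemistry simulator that generates genomes, ground-truth
    modification states, spike-ins, conversion counts and linked expression
    values for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
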