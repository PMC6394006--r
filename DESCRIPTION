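Package: chip2c
Title: Primer Panel Design and Quantification for Ligation-Mediated Targeted ChIP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computational support for carbon copy-ChIP (2C-ChIP), a
    ligation-mediated-amplification assay that quantifies chromatin
    immunoprecipitation signal over predefined genomic regions by sequencing
    barcoded ligation products. Provides primer panel design under homology
    length, GC, uniqueness and self-complementarity constraints; construction
    of the expected-product reference assemblies (all barcode x forward x
    reverse combinations plus unpaired primer sequences); a ground-truth read
    simulator; two-step read assignment with barcode demultiplexing; the
    input-normalization chain yielding ChIP/input ratio tracks in bedGraph
    format; and quality-control statistics including off-diagonal ligation
    accounting, titration linearity assessment, and correlation with
    ChIP-qPCR or ChIP-seq measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
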