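Package: clonetrace
Title: Clonal Genomics of Single-Cell-Derived Tumour Organoids
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing somatic mutation data from single-cell-derived
    tumour organoids and bulk biopsies: mutation-sharing classification
    (trunk / semi-private / private), trinucleotide mutational spectra with
    triplet-prevalence normalisation and supervised signature decomposition,
    Monte-Carlo gene-size enrichment testing, read-depth copy-number
    segmentation with panel-of-normals filtering, perfect-phylogeny clonal
    tree reconstruction, and mutation-rate regression. Ships a synthetic
    clonal-evolution simulator (time-constant substitution accrual, Tp53-gated
    copy-number alterations) and a toy genome builder so the whole pipeline is
    testable offline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
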