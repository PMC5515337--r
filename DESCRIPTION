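Package: felclone
Title: Clonal Relatedness of Multifocal Fibroepithelial Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to assess whether synchronous fibroepithelial breast
    lesions (fibroadenomas and phyllodes tumors) from one patient are
    clonally related. Implements a chance-sharing probability test for
    identical hotspot mutations based on reference-cohort frequencies, a
    simplified tumor-cell-fraction estimator with exact binomial intervals
    for clonal/subclonal classification, a copy-number breakpoint
    partial-identity score with a null-calibrated relatedness cutoff, and a
    synthetic multi-lesion cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
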