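Package: ctdnacall
Title: Error-Corrected Detection of Patient-Specific Tumour Mutations in
    Plasma Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Personalised circulating tumour DNA (ctDNA) detection from
    multiplex PCR amplicon sequencing of patient-specific somatic mutation
    panels. Implements paired-end consensus merging with discordant-base
    masking, primer-dimer screening, primer-anchored read counting, an exact
    conditional test of the ratio of two Poisson rates against same-run
    negative controls, ROC-based significance-cutoff calibration,
    dilution-series linearity and limit-of-detection analysis, and a
    synthetic-read generator emulating the genome-equivalents template
    bottleneck of cell-free DNA.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
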