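Package: pcsrscan
Title: Prediction of Potential Cancer-Susceptibility Regions from
    Multi-Cancer Transcriptome Alterations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts potential cancer-susceptibility regions (PCSRs) by
    scoring cytogenetic bands for their load of expression-altered microarray
    probesets across a panel of human cancers. Provides per-study differential
    calls (Welch t-test with symmetric fold-change thresholds), per-band and
    per-chromosome participation percentages with top-k region selection and a
    chi-square chromosome participation test, digital differential display
    screening of EST pools with Fisher's exact test, cross-cancer integration
    of altered mRNAs/miRNAs with expression-class assignment and same-band
    miRNA cluster detection, position-weight-matrix promoter scanning with
    relative profile scores and a pscan-style enrichment z-test, a synthetic
    data generator with planted region-level enrichment for end-to-end
    testing, and a deterministic pipeline driver that writes report tables.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
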