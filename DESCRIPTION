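Package: breakmark
Title: Mapping dsODN-Marked DNA Double-Strand Breaks from Ligation-Mediated PCR Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects CRISPR/Cas9 cleavage and spontaneous double-strand-break
    sites from double-stranded oligodeoxynucleotide (dsODN) marked,
    ligation-mediated PCR sequencing reads. Implements reporter-based removal
    of mispriming artifacts, sonication fragment-length clonal abundance
    ("inferred cells"), near-match protospacer/PAM scanning for on/off-target
    annotation, a primer flank-score mispriming diagnostic, and ROC-area
    association of break sites with genomic annotation tracks. Ships a
    synthetic-data generator that emulates the full amplicon grammar so every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
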