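Package: IntraProm
Title: Intragenic Promoter Feature Profiling and Nested Transcript Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Profiles a genomic region for promoter-like features by binning it
    into fixed-width modules and counting cross-cell-type hotspot prevalence
    (DNase I hypersensitivity, H3K4me3), scanning for initiator (INR) core
    promoter elements with a normalized position weight matrix score,
    tallying stranded CAGE-derived transcription start site predictions per
    module, reconstructing candidate nested transcripts from expressed
    sequence tags via center-star multiple alignment and consensus calling,
    and verifying primer designs by in-silico PCR. A seeded synthetic-data
    generator emulates ENCODE-style inputs so the complete analysis runs
    offline and deterministically.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
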