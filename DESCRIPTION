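Package: metaprofiler
Title: Metagene Profiles of ChIP-Seq Enrichment with Background
    Correction, Bootstrap Ribbons and Profile Similarity Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Aggregates ChIP-Seq read coverage over groups of genomic
    regions into background-corrected, library-size normalized metagene
    profiles. Controls are scaled with a signal-to-noise estimate (NCIS
    approach) before background subtraction, coverage is converted to
    reads per million, and per-group mean or median profiles carry
    bootstrap percentile confidence ribbons. Profiles are compared
    quantitatively with a permutation test under a user-chosen metric and
    with six profile-similarity pseudometrics, including an
    intersection-ratio rule that classifies factor occupancy into
    gradient versus threshold recruitment patterns. A seeded synthetic
    read simulator with known enrichment structure makes every pipeline
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    ggplot2,
    grDevices,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
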