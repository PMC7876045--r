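Package: sigmapause
Title: Calling and Characterizing Sigma70-Dependent Transcription Pauses
    from Nascent-RNA 3' End Data
Version: 0.1.0
Authors@R:
    person("RNET-seq", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of RNase-footprinted nascent elongating
    transcript sequencing (RNET-seq) in bacteria. Builds strand-specific
    3' end count tracks from aligned reads, calls transcription pause
    sites by a sliding-window median pause score with a counts-per-million
    floor, classifies pauses by their distance from the nearest
    same-strand transcription start site (G0/G1p/G1d/G2), annotates the
    promoter determinants of promoter-proximal pausing (-10 element
    individual information, spacer length, the YRY motif at the start
    site, and the downstream -10-like region), summarizes RNase-protected
    footprint lengths as RNA polymerase translocation states, compares
    pause sets between strains, and simulates synthetic genomes and
    nascent-read datasets with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
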