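Package: quadstop
Title: RNA G-Quadruplex Detection from Reverse-Transcriptase Stalling Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting RNA G-quadruplexes (rG4s) from paired
    K+/Li+ reverse-transcriptase stalling (RTS) sequencing libraries.
    Provides an in-silico model of deoxyuridine-adapter library chemistry
    (ligation, USER II scission, gel-quantification metrics), a seeded
    simulator of UMI-tagged rG4-seq read libraries with planted quadruplex
    motifs, UMI deduplication with stage-wise yield accounting and
    saturation analysis, per-position K+ versus Li+ stop testing with exact
    conditional tests and Benjamini-Hochberg control, merging of stalled
    positions into RTS sites, sequence-based structural classification of
    sites (canonical, long-loop, bulged, two-quartet, G-triplex), and
    benchmarking utilities: replicate intersection and consensus/union
    lists, coverage regression, 5'-nucleotide bias statistics with the
    Alexander-Govern test, TPM quantification and RNA-input guidelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
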