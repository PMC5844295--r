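Package: replicheck
Title: Replication-Based Purging of False-Positive Induced Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and removes systematic false-positive variant calls from
    low-coverage sequencing of a population of independently mutagenized
    lines. Because a chemical mutagen such as EMS hits essentially random
    positions, a variant called at the same genomic position in two or more
    independent lines is almost certainly a recurrent artifact rather than an
    induced mutation. The package provides the standard quality/depth/strand
    filter chain for per-line VCF calls, cross-population tallying of variant
    positions, construction and application of an error-prone position
    catalog, detection of contaminated (sibling) line pairs by pairwise call
    overlap, signal-to-noise based recovery of tentative false negatives, the
    same replicate machinery for indels keyed by event start, mutational
    spectrum and sequence-context diagnostics, an ungapped paralog scanner
    that explains recurrent artifacts, and a synthetic-population simulator
    with a machine-readable truth log for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
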