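Package: dnastore
Title: DNA-Based Information Storage with Low-Density Parity-Check Error Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Encodes arbitrary binary payloads into addressable 720-base DNA
    information blocks (LZMA compression, non-overlapping fragmentation,
    regular LDPC channel coding, quaternary base mapping) and recovers them
    from simulated short sequencing reads via quality trimming, greedy
    seed-extension overlay-consensus assembly and sum-product belief
    propagation decoding. Includes seeded base-substitution and
    Illumina-like paired-read error channels, an error-tolerance sweep and a
    coverage down-sampling study, plus FASTA/FASTQ and XML container I/O and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    xml2,
    withr,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
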