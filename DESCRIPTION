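Package: fqcm
Title: Lossless FASTQ Compression with Finite-Context Models and Context Mixing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained lossless compressor for FASTQ sequencing data.
    Records are decoupled into four homogeneous streams (read identifiers,
    nucleotide sequences, plus-lines, quality scores). Identifiers are
    tokenized and delta-coded, then compressed with single finite-context
    models; sequences are compressed with competing finite-context models of
    several orders; quality scores are compressed with a context-mixing
    bit predictor; all streams share one adaptive binary/multi-symbol range
    coder. Payloads are packed into a single checksummed binary archive and
    decompression reproduces the input byte-for-byte. Includes a seeded
    synthetic FASTQ generator (Illumina-like fixed-length and PacBio-like
    variable-length reads with correlated quality scores), a benchmark
    harness (compression ratio, speed, peak memory) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: POSIX (fork/wait4 are used for child-process benchmarking)
Config/testthat/edition: 3
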