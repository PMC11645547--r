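Package: copymix
Title: Reference-Free Genomic Sequence Compression with Context and Copy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless, reference-free compression of DNA sequences in FASTA and
    FASTQ files using order-k finite-context models, substitution-tolerant
    context models and repeat (copy) models whose predictions are combined by
    soft-blending with per-model forgetting factors and driven through an
    adaptive arithmetic coder. Ships preset model ensembles in three groups
    (efficient, optimized, maximal), a deterministic synthetic-sequence
    generator for calibration, and compression-based analysis outputs:
    per-symbol bit information, bit rates and Normalized Compression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
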