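Package: atacfoot
Title: Bias-Corrected ATAC-Seq Footprinting with Semi-Supervised Hidden
    Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcription-factor footprints in ATAC-seq (and
    DNase-seq) libraries. Strand-specific cleavage-event signals are
    decomposed by nucleosome fragment-size class, corrected for Tn5
    sequence cleavage bias with k-mer, PWM, or sparse local inhomogeneous
    mixture (SLIM) models, normalized, and decoded by a semi-supervised
    hidden Markov model with multivariate Gaussian emissions into
    footprint calls. Includes motif matching at a fixed false-positive
    rate, ChIP-seq-based footprint evaluation (partial AUC/AUPR and a
    combined ranking score), a differential transcription-factor activity
    score with median-of-ratios normalization, and a synthetic-library
    generator used as the test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
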