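Package: ecfscan
Title: Off-Target Promoter Prediction for Heterologous ECF Sigma Factors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects transcription start sites (TSS) from Cappable-seq-style
    per-base 5'-end read counts, scans DNA for bipartite -35/-10 promoter
    motifs of extracytoplasmic-function (ECF) sigma factors using
    position-specific scoring matrices with composition-matched empirical
    E-values, calibrates genome-scan score cutoffs from differential-expression
    evidence via Pareto-optimal promoter hits, and predicts off-target
    promoters in windows around annotated genome features. A synthetic-data
    generator with known ground truth supports end-to-end parameter-recovery
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
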