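Package: ssindex
Title: Sparse Selection Indices for Multi-Generation Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genomic prediction over linear (additive genomic relationship)
    and non-linear (Gaussian) kernels, with per-individual L1-penalized
    sparse selection indices solved by coordinate descent along a penalty
    path and tuned by k-fold cross-validation.  Includes BLUP baselines,
    REML and Gibbs variance-component estimation, variance-weighted kernel
    averaging, dominant-marker quality control (segregation-distortion and
    minor-allele-frequency filters), adjusted-phenotype (BLUE) computation
    from incomplete-block trial records, a multi-generation doubled-haploid
    population simulator, and scenario-based accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
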