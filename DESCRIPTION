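Package: qpcrstab
Title: Reference Gene Stability Analysis for RT-qPCR with Efficiency
    Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Validation of candidate reference (housekeeping) genes for
    RT-qPCR normalization. Implements the four standard stability
    statistics (geNorm M with pairwise variation V, BestKeeper
    descriptive statistics and index correlation, the model-based
    NormFinder estimator, and the pairwise delta-Ct method), a
    geometric-mean-of-ranks comprehensive ranking, amplification
    efficiency estimation from dilution-series standard curves,
    per-assay efficiency correction of quantification cycles, positional
    comparison of rankings computed from raw versus efficiency-corrected
    Cq, and efficiency-weighted relative quantification of target genes
    against multi-gene normalization factors. Includes a synthetic Cq
    data generator with the variance components (sample loading,
    per-gene stability noise, condition effects, technical replication)
    that reference-gene analysis assumes, so the whole pipeline is
    testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
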