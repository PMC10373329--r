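Package: mcqsar
Title: Monte Carlo Correlation-Weight QSAR with Hybrid SMILES/Graph Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds one-descriptor QSAR regression models from correlation
    weights of SMILES attributes and hydrogen-suppressed-graph invariants,
    optimized by Monte Carlo hill climbing under balance-of-correlation target
    functions with the index of ideality of correlation (IIC). Includes the
    external-validation battery (Q2, CCC, rm2 metrics, Y-scrambling), an
    applicability domain based on attribute statistical defects, promoter
    classification of structural attributes across replicate runs, and a
    synthetic flavonol-like library generator with planted structure-activity
    signal for end-to-end testing. Ships an 80-compound flavonol anti-prostate
    cancer (PC-3 pIC50) dataset with three training/invisible-training/
    calibration/validation splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
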