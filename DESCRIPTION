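Package: pairscan
Title: Pairwise Genetic Effect Detection for Quantitative Traits by Robust
    Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies pairwise genetic effects - additive
    effects versus genetic interactions (epistasis) - on quantitative lipid
    traits and binary disease status. Implements a four-model robust linear
    regression battery (Huber M-estimation with iteratively reweighted least
    squares), Schwarz information criterion model selection, normal-theory
    p-values and Benjamini-Hochberg false discovery rate families for
    gene-burden, SNP dosage, burden-by-SNP and burden-by-polygenic-score
    designs, together with the companion combinatorial RNAi screen statistics:
    per-array robust Z-scores against negative controls, a five-model
    interaction battery, delta-BIC evidence grading, a genetic-interaction
    taxonomy (aggravating, alleviating, suppressive) and a validation rule.
    Synthetic cohort and screen generators with exportable planted truth
    support power, calibration and recovery analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
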