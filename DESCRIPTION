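Package: gicompare
Title: Comparison, Error Modeling and Combination of Quantitative Genetic
    Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare quantitative genetic interaction (epistasis)
    networks mapped under different phenotypic readouts, environmental
    conditions and laboratories. Implements pairwise comparison measures
    (Spearman correlation of interaction scores, Jaccard overlap, unique
    and sign-disagreement fractions of binarized interactions), an
    analytic model of the network overlap expected from per-sign
    sensitivity and precision with a Monte-Carlo oracle, genetic
    interaction profile similarity networks and their maximum-correlation
    combination, a guilt-by-association gene function prediction benchmark
    (Gaussian-field label propagation, five-fold cross-validated AUROC and
    AUPR per GO term), hierarchical clustering of all-versus-all dataset
    similarity matrices, and a synthetic multi-dataset screen generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
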