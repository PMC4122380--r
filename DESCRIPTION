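Package: tracegrn
Title: Ensemble Inference and Inferability of Gene Regulatory Networks
    from Knock-Out Expression Data
Version: 0.1.0
Authors@R:
    person("tracegrn", "maintainers", email = "maintainers@tracegrn.example.org",
           role = c("aut", "cre"))
Description: Ensemble inference of gene regulatory networks from
    steady-state gene knock-out expression data. Differential expression
    (trimmed z-scores) is converted into gene accessibility matrices, from
    which provable lower and upper bounds of the ensemble of all networks
    consistent with the data are constructed via transitive closure,
    transitive reduction and strong-component condensation. Includes
    majority-vote error correction with a testable-edge filter,
    inferability analysis of knock-out experimental designs, ranked edge
    predictions with confidence scores, masked AUROC/AUPR evaluation, and
    synthetic-data generators (random and scale-free networks, error
    injection, a simplified knock-out expression simulator).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
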