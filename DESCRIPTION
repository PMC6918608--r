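Package: lpsda
Title: Label-Propagation Enhanced Drug Safety Signal Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects drug safety signals from spontaneous adverse-event case
    reports with four disproportionality algorithms (PRR05, ROR05, the
    empirical-Bayes gamma-Poisson shrinker EB05, and the Bayesian confidence
    propagation neural network lower bound BCPNN25), then enhances the scores
    by label propagation over a drug-drug chemical similarity network built
    from binary substructure fingerprints. Includes the full evaluation
    protocol (AUC/AUPR with 2:1 negative sampling, absorbing-probability grid
    search, per-reaction evaluation, cumulative-year curves), scoring of newly
    approved drugs with no reports, and a planted-cluster synthetic data
    generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
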