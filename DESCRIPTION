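Package: morphotest
Title: Evaluating Semi-Diagnostic Characters for Species Identification in
    Hybrid Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating a binary semi-diagnostic character (a shell
    morphotype) as a probabilistic species-identification test in hybrid zones
    between blue mussels Mytilus edulis and M. trossulus. Computes per-sample
    diagnostic indices (sensitivity, false-positive rate, positive and
    negative predictive values), prevalence-dependent Bayes calculators linking
    morphotype frequency to taxonomic structure, binomial GLM/GLMM regressions
    of morphotype and identification-correctness on prevalence with
    Nakagawa-Schielzeth pseudo-R2, a calibration-pair experiment ranking
    candidate calibration samples by a pair-dissimilarity index against
    regression references, a per-sample morphotype-size screen with Hochberg
    correction, and a synthetic hybrid-zone data generator emulating bimodal
    and flattened admixture-proportion distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    parallel,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
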