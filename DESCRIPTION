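Package: radboot
Title: Bootstrapped Evaluation of Radiomics Outcome Models for Brain Metastasis Radiosurgery
Version: 0.1.0
Authors@R:
    person("radboot", "authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A patient-level bootstrapped evaluation framework for per-metastasis
    progression models after stereotactic radiosurgery. Provides a synthetic cohort
    generator emulating a 99-patient / 123-metastasis study sample, image
    normalisation contracts (z-score with clipping, isotropic trilinear resampling,
    fixed-bin-count discretisation), a 250-repetition patient-level bootstrap engine
    around an internal random decision forest with out-of-bag bookkeeping, pooled
    ROC error metrics with the .632+ bootstrap AUC correction and out-of-bag
    operating-point transfer, volume-decorrelation feature filtering with a
    Bonferroni-controlled threshold sweep, normalized feature-importance
    aggregation, and stratified re-aggregation of error metrics by primary cancer
    site, lesion volume group, and scanner model pairing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
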