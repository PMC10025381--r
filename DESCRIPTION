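Package: hybridcv
Title: Training-Set Designs for Genomic Prediction in Unreplicated
    Testcross Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genomic prediction of maize testcross hybrids evaluated in
    unreplicated multi-environment field trials. Provides a breeding-program
    simulator (two heterotic pools of doubled-haploid lines, tester x
    candidate trial layouts, multi-environment phenotypes), SNP marker and
    line quality control with Rogers' distance, linkage-disequilibrium and
    principal-component diagnostics, adjustment of plot values for year and
    location-within-year effects, two-pool marker-effect models fitted by
    RR-BLUP (REML) and by Bayesian whole-genome regression (Bayesian ridge,
    Bayes A, Bayes B), and a replicated cross-validation engine implementing
    eight training-set designs (within-environment, within-year and
    across-year prediction) scored by per-environment Pearson accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
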