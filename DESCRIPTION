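Package: morphodev
Title: Multi-Site Brain Morphometry: Harmonization, Normative Deviations
    and Leakage-Safe Classification
Version: 0.1.0
Authors@R: person("morphodev", "maintainers", email = "morphodev@example.org",
    role = c("aut", "cre"))
Description: Tools for case-control analyses of regional brain morphometry
    pooled across imaging sites. Implements empirical-Bayes site-effect
    harmonization with a nonlinear (spline) age term (ComBat-GAM style),
    per-metric general linear models with covariate-adjusted Cohen's d and
    Benjamini-Hochberg FDR, normative-deviation z-scoring with exact binomial
    exceedance tests and bootstrap heterogeneity indices, and a leakage-safe
    classification pipeline (confound regression, PCA, class-weighted linear
    SVM) under stratified nested cross-validation with in-fold harmonization
    and leave-site-out evaluation. A synthetic multi-site cohort generator
    emulating an anorexia-nervosa case-control consortium is included for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
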