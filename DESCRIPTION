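Package: mrpath
Title: Two-Sample Mendelian Randomization with Stepwise Mediation for the
    Hepato-Ovarian Axis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Instrument selection, harmonization, and two-sample Mendelian
    randomization (MR) from GWAS summary statistics, built around the causal
    pathway from non-alcoholic fatty liver disease (NAFLD) to polycystic
    ovary syndrome (PCOS) via fasting insulin and sex hormones. Provides
    inverse-variance weighted, MR-Egger, weighted-median and leave-one-out
    estimators, an MR-PRESSO outlier test, multivariable MR with conditional
    F statistics, product-of-coefficients mediation with multivariate
    delta-method intervals, fixed-effects meta-analysis, a minimal LD-score
    regression for heritability and genetic correlation, and a summary-level
    GWAS simulator with known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), metafor, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ldsc.R'
    'summary-data.R'
    'mr-core.R'
    'mvmr.R'
    'mediation.R'
    'mr-presso.R'
    'simulate.R'
    'pipeline.R'
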