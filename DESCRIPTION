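Package: plateletMR
Title: Two-Sample Mendelian Randomization for Platelet Count and
    Cardiovascular Outcomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics, built around the genetically determined platelet count to
    cardiovascular disease analysis design. Reads and harmonizes
    exposure/outcome association tables, validates instrument strength
    (F statistics), computes per-SNP Wald ratios with delta-method standard
    errors, and pools them with fixed-effect inverse-variance weighting,
    MR-Egger regression, the weighted median, and the weighted mode-based
    estimator. A full pleiotropy battery is included: Cochran Q and I2
    heterogeneity, Rucker model selection, I2GX instrument-strength
    heterogeneity, MR-PRESSO global/outlier/distortion tests, and funnel and
    radial plot data. A synthetic summary-statistics generator with known
    causal truth supports calibration and recovery studies, and a
    config-driven study runner orchestrates multi-outcome analyses with
    tiered significance thresholds.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'wald.R'
    'estimators.R'
    'heterogeneity.R'
    'methods-accessors.R'
    'plots-data.R'
    'presso.R'
    'summary-io.R'
    'simulate.R'
    'study.R'
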