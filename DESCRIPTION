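Package: prscreen
Title: Polygenic Risk Scores Across Ordered Colorectal Screening Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation pipeline for a polygenic risk score (PRS) in a fecal
    immunochemical test (FIT)-based colorectal cancer screening setting.
    Reads a SNP weight panel and genotype dosages (VCF or plain tables),
    applies standard variant and sample quality-control filters
    (Hardy-Weinberg equilibrium, minor allele frequency, missingness,
    imputation quality), computes unweighted and beta-weighted risk scores,
    adjusts them for sex, age, genotyping array, family history and genetic
    ancestry principal components, and evaluates discrimination and clinical
    utility across an ordered seven-level outcome (population controls
    through clinically diagnosed cancer): Mann-Kendall trend tests,
    cross-validated ROC curves with DeLong comparisons, per-variant logistic
    associations, control-decile odds ratios, and positive/negative
    predictive value curves reweighted to the source population by FIT
    stratum. A liability-threshold cohort simulator generates screening
    cohorts with severity-dependent FIT positivity and FIT-stratified
    sampling, calibrated so the full pipeline reproduces realistic
    discrimination levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    pROC,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
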