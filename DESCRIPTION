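Package: metsynir
Title: Insulin Resistance Surrogate Indices and Metabolic Syndrome Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the relationship between surrogate insulin
    resistance indices and metabolic syndrome in adult cohorts. Computes the
    TyG index and its anthropometric variants (TyG-BMI, TyG-waist, TyG-WtHR),
    the triglyceride/HDL ratio and METS-IR, together with Friedewald LDL;
    classifies metabolic syndrome under the NCEP/ATP-III, IDF and JIS
    criteria; and provides ROC curves with DeLong confidence intervals,
    Youden-optimal cut-points, and logistic-regression odds ratios relating
    the indices to syndrome status. A seeded Gaussian-copula cohort simulator
    calibrated to published sex-stratified population characteristics supplies
    reproducible synthetic data for the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
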