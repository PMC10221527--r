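Package: gutlink
Title: Gut Microbiota to Serum Metabolome Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline linking gut-location-specific microbial taxa
    profiles to serum metabolite features. Provides taxa-table
    preprocessing (rarefaction, abundance and prevalence filtering,
    alpha diversity, Bray-Curtis ordination, ANOSIM), LC-MS feature
    matrix quality control (missingness filters, QC-anchored drift
    correction, RSD filtering, annotation-level selection), a two-part
    presence/abundance association model combined by unweighted
    Z-score meta-analysis with Benjamini-Hochberg FDR control,
    covariate-adjusted Spearman validation, cross-location shared
    association detection, cross-validated variance-explained
    estimation, and a metabolite biomarker-panel workflow (PLS-DA VIP
    scores, stepwise logistic regression, ROC/AUC). A synthetic-cohort
    generator with implanted taxon-metabolite effects makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
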