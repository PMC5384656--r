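Package: ptbdnm
Title: De Novo Mutation Burden and Developmental Consequences in Preterm Birth Trio Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fetal de novo mutation studies of preterm
    birth. Computes per-genome autosomal mutation burden from trio cohorts and
    tests case/control differences with paternal- and maternal-age confounder
    handling (rank-sum tests with an exact small-sample path, burden
    residualization, z-scored logistic regression); filters nonsynonymous
    mutations by CADD deleteriousness to extract affected gene sets and
    characterizes them by copy-number intolerance, mouse-knockout viability,
    and phenotype-term enrichment with BH-FDR; scores developmental expression
    propensity (early-fetal vs postnatal fold change) over a staged brain
    expression matrix; and classifies copy-number-variable regions as shared
    with or novel to a reference collection by an 80 percent coverage rule.
    Includes a calibrated synthetic cohort generator so the full pipeline is
    testable without access to the original cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    methods,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
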