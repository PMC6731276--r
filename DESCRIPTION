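Package: pathchemo
Title: Integrative Transcriptomic and Epigenomic Pathway Discovery for
    Chemotherapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies molecular pathways altered on both the mRNA
    expression and DNA methylation level between extreme responders to a
    chemotherapy regimen, and validates them as predictors of treatment
    resistance. Differential expression and methylation signatures are
    subjected to signed and absolute-valued gene set enrichment analysis
    with permutation-based normalized enrichment scores; the two modes are
    integrated per pathway by the lowest p-value, and a pathway-level
    enrichment with query-threshold optimization selects pathways
    significant on both molecular levels, followed by Fisher-exact
    redundancy pruning. Validation tools include single-sample pathway
    activity scoring, t-SNE two-group patient stratification,
    Kaplan-Meier/log-rank and Cox proportional-hazards analysis, random
    pathway and random group null models, leave-one-out cross-validated
    risk prediction, and read-out gene selection by combining activity
    correlation with survival association via Fisher's method. A synthetic
    multi-omics cohort generator with planted pathway alterations and
    activity-coupled survival makes the full pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
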