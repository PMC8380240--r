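Package: dilimet
Title: Serum Metabolomics Phenotyping of Drug-Induced Liver Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for untargeted LC-MS serum metabolomics of
    drug-induced liver injury (DILI). Implements QC-based support-vector
    regression drift correction (QC-SVRC) with leave-one-out grid search,
    D-ratio*, blank and group-intensity quality filters, bridge-sample
    between-batch scaling, Welch t screening with Benjamini-Hochberg FDR,
    one-vs-rest PLS-DA with NIPALS, VIP scores, subjectwise double
    cross-validation, AUROC and patient-level permutation testing, and the
    mapping of constrained class predictions onto a ternary phenotype
    simplex (cholestatic, hepatocellular, recovered) for classification
    and longitudinal monitoring. Includes a synthetic study generator that
    emulates the batch structure, signal drift and phenotype-dependent
    metabolite effects the analysis assumes, plus the clinical R-score and
    rule-based DILI phenotype classification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    ggplot2,
    withr
Config/testthat/edition: 3
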