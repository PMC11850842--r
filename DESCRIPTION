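Package: methrx
Title: Prescription-Derived Drug Exposure and Whole-Blood Methylome
    Association Analysis
Version: 0.1.0
Authors@R:
    person("methrx", "maintainers", email = "methrx@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline linking drug exposure to whole-blood DNA
    methylation. Derives a prescription-based exposure phenotype from
    dispensing records (treatment-episode construction with lead/tail
    rules at blood draw), runs a methylome-wide association study with a
    mixed linear model using an omics-relatedness random effect after
    BLUP residualization on a kinship matrix, detects differentially
    methylated regions by correlation-adjusted inverse-variance
    meta-analysis, tests cross-study concordance with hypergeometric
    overlap and circular-permutation enrichment, and trains a sparse
    methylation profile score by cross-validated LASSO that is scored in
    external cohorts and pooled by DerSimonian-Laird random-effects
    meta-analysis. Includes a synthetic-cohort generator emulating
    family relatedness, locally correlated probes, confounding, and
    prescription streams so the whole pipeline is testable without any
    cohort download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
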