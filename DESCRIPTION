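Package: ratxcan
Title: Transcriptome-Wide Association in Related Cohorts with Mixed-Effects Whitening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Trains cis elastic-net gene-expression prediction models, imputes
    genetically regulated expression into a target cohort, and tests gene-trait
    associations while correcting for relatedness and polygenicity by whitening
    phenotype and predicted expression with the inverse matrix square root of
    the trait covariance implied by the genetic relatedness matrix (GRM).
    Includes a pedigree gene-dropping synthetic-cohort generator, a
    null-phenotype type-I-error calibration study, Cauchy-combination (ACAT)
    aggregation of per-tissue p-values, and cross-species ortholog enrichment
    against external gene-level association results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    DBI,
    RSQLite,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
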