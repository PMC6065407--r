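Package: concord
Title: Tumor-Organoid Genomic Concordance and Clonal Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how faithfully patient-derived cancer
    organoids recapitulate the tumors they came from, and how their clonal
    composition evolves over serial passages. Implements somatic-variant
    concordance with pooled-sample rescue, mutational-signature exposure
    fitting by non-negative least squares with subtype assignment,
    ploidy-relative copy-number and structural-variant classification,
    cancer-cell-fraction estimation with Dirichlet-process subclone
    clustering, cluster quality control and sum/crossing tree rules,
    expressed-mutation and patient-specific expression-signature
    concordance, and dose-response drug-screen profiling (IC50, AUC,
    Z-factor). A seeded synthetic paired-cohort generator with known clone
    trees, exposures, purities and drug sensitivities makes every stage
    testable without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
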