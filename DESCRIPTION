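Package: methylpanel
Title: Methylation-Array Analysis of Fibrotic Progression in Prefibrotic
    Primary Myelofibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide DNA-methylation analysis pipeline for EPIC-style
    beta-value matrices, built around the discrimination of prefibrotic
    primary myelofibrosis patients with later fibrotic progression from
    those with stable disease. Covers detection-p filtering, BMIQ
    intra-sample normalization, ComBat batch correction and SVD confounder
    screening; moderated-t differential methylation, bump-hunting
    differentially methylated regions and probe-bias-aware gene-set
    enrichment; exact branch-and-bound selection of minimal CpG panels on
    the tau-squared criterion with linear discriminant classification and
    repeated cross-validation; methylation-derived copy-number profiling;
    epigenetic-clock age statistics; and cohort-level methylation
    accounting. A synthetic-cohort generator with known planted structure
    stands in for patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    sva,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
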