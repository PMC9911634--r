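Package: ithsig
Title: Intra-Tumor Heterogeneity-Aware Immune Signatures from Multi-Region RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies gene-wise intra-tumor heterogeneity from multi-region
    bulk RNA-seq with an integrated heterogeneity score (IHS) that combines a
    one-way random-effects variance decomposition (intraclass correlation) with
    a subclonal expression-event frequency, identifies immune expression modules
    by non-negative matrix factorization, derives heterogeneity-robust inflamed
    signatures by intersecting immune-module genes with low-IHS genes, scores
    and classifies tumors into inflamed and non-inflamed classes by tertiles,
    and evaluates per-patient classification concordance across intra-tumor
    regions. Includes a synthetic multi-region cohort simulator with known
    clonal and subclonal structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
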