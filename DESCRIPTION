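Package: urosig
Title: Derivation, Scoring and Outcome Analysis of an Urothelial
    IFN-Gamma Response Gene Signature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for deriving an interferon-gamma
    (IFN-gamma) response gene signature from paired in vitro urothelial
    expression data, refining it by correlation consensus across tumour
    cohorts, computing a single-value per-tumour signature score, stratifying
    tumours into signature-high and signature-low groups by k-means,
    comparing groups by Kaplan-Meier, log-rank (Mantel-Cox),
    Gehan-Breslow-Wilcoxon and Cox proportional-hazards analysis, and
    associating the score with APOBEC mutational-signature exposures and
    neoantigen load. Includes a synthetic-cohort generator with planted
    ground truth so every stage is testable without external downloads.
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
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
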