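Package: npcomb
Title: Non-Parametric Combination of Partially Paired Multi-Omics Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Permutation-based non-parametric combination (NPC) of per-dataset
    differential tests for studies in which two (or more) datasets share a
    subset of individuals. Per-feature linear models with covariates provide
    partial F statistics; disease labels are permuted at the individual level
    so that paired individuals keep identical labels across datasets, partial
    permutation p-values are combined with the Liptak (Stouffer) function, and
    global p-values are read off the permutation null of the combined
    statistic. Includes downstream cis expression-methylation correlation
    screening around transcription start sites, rank-based gene-set
    enrichment, a synthetic paired multi-omics study generator with ground
    truth, and a configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
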