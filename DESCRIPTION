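Package: foltile
Title: Tile-Based Differential Methylation and Folate-Exposure Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for intergenerational folate-diet studies in the
    mouse: 100-bp tile aggregation of reduced representation bisulphite
    sequencing (RRBS) CpG count tables, logistic likelihood-ratio / Fisher
    exact calling of differentially methylated tiles (DMTs) with
    Benjamini-Hochberg correction, genomic feature annotation with intergenic
    enrichment testing and cross-tissue DMT intersection, classification of
    DMTs at maternally inherited methylation regions (sperm-low, oocyte/inner
    cell mass-high loci and their gain/stable/loss dynamics), LUMA and
    imprinted-gene pyrosequencing summaries, and litter-level reproductive
    outcome statistics (pre-/post-implantation loss, 2-SD growth
    classification, Fisher and Dunnett tests). Includes a full synthetic-data
    generator with planted effects so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    withr,
    multcomp,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
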