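Package: mirage
Title: Age-Stratified Evolutionary Analysis of miRNA Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dates the origin of miRNA gene families on a species phylogeny by
    maximum parsimony, fits a constant-birth/Gamma-survivorship turnover model
    to the resulting age distribution, and computes the downstream age-group
    statistics used in comparative miRNA studies: mature/seed sequence sharing
    between age groups, SNP and indel density by region class, Kimura
    two-parameter substitution rates under a molecular clock, normalized
    minimum-free-energy summaries, tissue-specificity and abundance scoring of
    small-RNA expression atlases, malignancy enrichment, target-set overlap,
    and host-gene age cross-tabulation. A seeded synthetic-data generator
    produces every input the pipeline consumes so all stages are testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
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
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
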