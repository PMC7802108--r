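Package: cellstainr
Title: Rank Tissue Cell Types by Immunohistochemistry Staining of a Gene List
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Queries pathologist-scored immunohistochemistry staining tables
    (Human Protein Atlas style) with a list of genes or proteins and ranks
    tissue cell types by a 0-100 staining score built from the counts of
    High, Medium and Low staining calls. Attaches a sample-size-aware
    confidence score, and tests each cell type for over-representation of
    rarely detected ("enriched") proteins with a one-sided Fisher exact test
    (or chi-squared), Holm-adjusted across cell types, under three
    antibody-reliability stringency levels. Includes a tissue/cell summary
    of proteins evaluated versus positively stained, permutation null
    distributions of the staining score from random gene lists, and a
    synthetic atlas generator so the whole pipeline is testable without
    downloading atlas data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
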