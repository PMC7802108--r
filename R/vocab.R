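# Closed vocabularies of the staining atlas dialect, plus the score weights
# attached to each staining level.

stain_levels <- c("High", "Medium", "Low", "Not detected")
positive_levels <- c("High", "Medium", "Low")
level_weights <- c(High = 100, Medium = 50, Low = 25, `Not detected` = 0)
reliability_levels <- c("Enhanced", "Supported", "Approved", "Uncertain")

#' Antibody-reliability labels admitted at a stringency level
#'
#' Staining records carry an antibody-evidence label (`Enhanced`, `Supported`,
#' `Approved`, `Uncertain`, in decreasing order of certainty). The stringency
#' setting decides which labels are kept before any scoring or enrichment
#' computation: `"low"` keeps all four, `"normal"` drops `Uncertain`, and
#' `"high"` keeps only `Enhanced` and `Supported`.
#'
#' @param stringency One of `"low"`, `"normal"`, `"high"`.
#' @return Character vector of admitted reliability labels.
#' @examples
#' stringency_reliabilities("high")
#' @export
stringency_reliabilities <- function(stringency = c("normal", "low", "high")) {
  stringency <- match.arg(stringency)
  switch(stringency,
    low = reliability_levels,
    normal = c("Enhanced", "Supported", "Approved"),
    high = c("Enhanced", "Supported")
  )
}

#' Canonical display label for a tissue/cell-type pair
#'
#' Scores attach to a (tissue, cell type) pair, displayed as
#' `"TISSUE - cell type"` with the tissue upper-cased. Matching of pairs is
#' case-insensitive and whitespace-trimmed.
#'
#' @param tissue,cell_type Character vectors (recycled together).
#' @return Character vector of display labels.
#' @examples
#' cell_type_key("pancreas", "exocrine glandular cells")
#' @export
cell_type_key <- function(tissue, cell_type) {
  paste0(toupper(stringr::str_squish(tissue)), " - ", stringr::str_squish(cell_type))
}

# Case-insensitive, trimmed match of x onto a closed vocabulary; NA where no
# member matches.
normalize_vocab <- function(x, vocab) {
  vocab[match(tolower(stringr::str_squish(x)), tolower(vocab))]
}

abort_cellstainr <- function(message, class, ...) {
  abort(message, class = c(paste0("cellstainr_error_", class), "cellstainr_error"), ...)
}
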