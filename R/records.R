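# Shared normalization of staining records: canonical gene symbol, display
# key, stringency filtering, and best-level deduplication.

require_columns <- function(records, cols, what) {
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    abort_cellstainr(
      paste0(what, " is missing required column(s): ", paste(missing, collapse = ", ")),
      "schema"
    )
  }
}

# Canonicalize a staining-record table: upper-cased symbol, display key, and
# the numeric weight of the level. Drops nothing.
normalize_records <- function(records) {
  require_columns(records, c("gene_name", "tissue", "cell_type", "level", "reliability"),
                  "staining-record table")
  if (nrow(records) == 0) abort_cellstainr("staining-record table is empty", "empty_input")
  dplyr::mutate(
    tibble::as_tibble(records),
    gene = toupper(stringr::str_squish(.data$gene_name)),
    display = cell_type_key(.data$tissue, .data$cell_type),
    weight = unname(level_weights[.data$level])
  )
}

filter_stringency <- function(records, stringency) {
  admitted <- stringency_reliabilities(stringency)
  out <- dplyr::filter(records, .data$reliability %in% admitted)
  if (nrow(out) == 0) {
    abort_cellstainr(
      paste0("no records left after '", stringency, "' stringency filtering"),
      "empty_after_filter"
    )
  }
  out
}

# One row per gene x display key, resolving duplicate records (multiple
# antibodies/samples) by best level wins: High > Medium > Low > Not detected.
dedup_best_level <- function(normalized) {
  normalized %>%
    dplyr::arrange(dplyr::desc(.data$weight)) %>%
    dplyr::distinct(.data$gene, .data$display, .keep_all = TRUE)
}

# Full normalize + filter + dedup pipeline used by scoring and enrichment.
prepare_records <- function(records, stringency) {
  records %>%
    normalize_records() %>%
    filter_stringency(stringency) %>%
    dedup_best_level()
}
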