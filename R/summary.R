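#' Summarize an atlas: proteins evaluated vs positively stained per cell type
#'
#' For every (tissue, cell type) pair, counts the distinct proteins with any
#' staining record (`n_evaluated`), the distinct proteins whose best level is
#' `Low`, `Medium` or `High` (`n_stained`), and the percentage stained.
#' `Not detected` counts as evaluated but not stained. Proteins are counted
#' once per cell type even when several records (antibodies/samples) exist.
#' No stringency filter is applied: the summary describes the raw table.
#'
#' @param records A staining-record tibble, e.g. from [read_normal_tissue()]
#'   or [generate_atlas()].
#' @return A tibble with one row per cell type: `tissue`, `cell_type`,
#'   `cell_type_key`, `n_evaluated`, `n_stained`, `pct_stained`, sorted by
#'   `pct_stained` descending.
#' @examples
#' summarize_atlas(worked_example_fixture())
#' @export
summarize_atlas <- function(records) {
  normalize_records(records) %>%
    dedup_best_level() %>%
    dplyr::group_by(.data$display) %>%
    dplyr::summarise(
      tissue = dplyr::first(.data$tissue),
      cell_type = dplyr::first(.data$cell_type),
      n_evaluated = dplyr::n(),
      n_stained = sum(.data$weight > 0),
      .groups = "drop"
    ) %>%
    dplyr::mutate(pct_stained = 100 * .data$n_stained / .data$n_evaluated) %>%
    dplyr::select(
      "tissue", "cell_type", cell_type_key = "display",
      "n_evaluated", "n_stained", "pct_stained"
    ) %>%
    dplyr::arrange(dplyr::desc(.data$pct_stained), .data$cell_type_key)
}
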