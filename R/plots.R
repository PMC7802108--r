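# ggplot2 views of the package's result objects.

#' Bar chart of the top-ranked cell types for a query
#'
#' @param object A `stain_ranking` from [score_query()].
#' @param top_n How many cell types to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stain_ranking
#' @export
autoplot.stain_ranking <- function(object, top_n = 15, ...) {
  df <- tidy(object) %>%
    dplyr::slice_head(n = top_n) %>%
    dplyr::mutate(cell_type_key = stats::reorder(.data$cell_type_key,
                                                 .data$staining_score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$staining_score,
                                   y = .data$cell_type_key,
                                   fill = .data$p_adjusted < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "grey60"),
      na.value = "grey80", name = "Holm p < 0.05"
    ) +
    ggplot2::labs(x = "staining score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histograms of permutation null staining scores by list size
#'
#' @param object A `stain_null` from [run_permutations()].
#' @param top_only Show only the top-k scores per run instead of all scores.
#' @param ... Unused.
#' @return A ggplot faceted by gene-list size.
#' @method autoplot stain_null
#' @export
autoplot.stain_null <- function(object, top_only = FALSE, ...) {
  df <- tibble::as_tibble(object)
  if (top_only) df <- dplyr::filter(df, .data$in_top_k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$staining_score)) +
    ggplot2::geom_histogram(bins = 40, fill = "#2166ac", colour = "white") +
    ggplot2::facet_wrap(~list_size, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "staining score", y = "count") +
    ggplot2::theme_minimal()
}
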