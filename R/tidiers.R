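# broom-style tidiers for the package's result objects.

#' Tidy a ranked query result
#'
#' @param x A `stain_ranking` from [score_query()] or [score_query_cancer()].
#' @param ... Unused.
#' @return A plain tibble of the result rows.
#' @method tidy stain_ranking
#' @export
tidy.stain_ranking <- function(x, ...) {
  out <- x
  attr(out, "meta") <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a ranked query result
#'
#' @param x A `stain_ranking`.
#' @param ... Unused.
#' @return A one-row tibble: query size, matched genes, scored cell types,
#'   the top hit and its scores, and how many cell types stay significant
#'   after Holm adjustment at 0.05.
#' @method glance stain_ranking
#' @export
glance.stain_ranking <- function(x, ...) {
  meta <- attr(x, "meta", exact = TRUE)
  tibble::tibble(
    n_query = meta$query$n_unique,
    n_matched = length(meta$matched),
    n_cell_types = nrow(x),
    top_cell_type = x$cell_type_key[1],
    top_staining_score = x$staining_score[1],
    top_confidence_score = x$confidence_score[1],
    n_significant = sum(x$p_adjusted < 0.05, na.rm = TRUE),
    stringency = meta$stringency,
    test = meta$test
  )
}

#' Tidy an enriched protein set
#'
#' @param x An `enriched_set` from [build_enriched_set()].
#' @param ... Unused.
#' @return A tibble of per-protein detection fractions with a logical
#'   `member` column (fraction at or below the first-quartile cutoff).
#' @method tidy enriched_set
#' @export
tidy.enriched_set <- function(x, ...) {
  dplyr::mutate(x$fractions, member = .data$gene %in% x$members)
}

#' One-row summary of an enriched protein set
#'
#' @param x An `enriched_set`.
#' @param ... Unused.
#' @return A one-row tibble: stringency, protein count, quartile cutoff and
#'   member count.
#' @method glance enriched_set
#' @export
glance.enriched_set <- function(x, ...) {
  tibble::tibble(
    stringency = x$stringency,
    n_proteins = nrow(x$fractions),
    threshold = x$threshold,
    n_members = length(x$members)
  )
}
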