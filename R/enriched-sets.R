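# Rare ("enriched") protein sets: per-protein detection fractions across cell
# types, and the first-quartile cutoff that defines set membership.

#' Per-protein detection fractions across cell types
#'
#' For each protein, computes the share of (tissue, cell type) pairs where its
#' best staining level is positive (`Low`/`Medium`/`High`) among the pairs
#' where it was evaluated at all, after filtering records by the stringency's
#' admitted reliability labels. Proteins that never stain positively anywhere
#' are excluded from the output.
#'
#' @param records A staining-record tibble.
#' @param stringency `"low"`, `"normal"` or `"high"`; see
#'   [stringency_reliabilities()].
#' @return A tibble with columns `gene`, `n_keys` (cell types evaluated),
#'   `n_positive`, `fraction`.
#' @export
detection_fractions <- function(records, stringency = "normal") {
  prepare_records(records, stringency) %>%
    fractions_from_dedup()
}

fractions_from_dedup <- function(dedup) {
  dedup %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      n_keys = dplyr::n(),
      n_positive = sum(.data$weight > 0),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_positive > 0) %>%
    dplyr::mutate(fraction = .data$n_positive / .data$n_keys) %>%
    dplyr::arrange(.data$fraction, .data$gene)
}

#' Detection fractions across cancers from patient-count records
#'
#' The cancer analogue of [detection_fractions()]: a gene counts as evaluated
#' in a cancer when it has any patient counted there, and as positive when at
#' least one patient stained `High`, `Medium` or `Low`. There is no
#' reliability column in cancer data, so no stringency filter applies.
#'
#' @param cancer_records A cancer staining tibble, e.g. from [read_cancer()].
#' @return A tibble with columns `gene`, `n_keys`, `n_positive`, `fraction`.
#' @export
detection_fractions_cancer <- function(cancer_records) {
  fractions_from_cancer(normalize_cancer_records(cancer_records))
}

fractions_from_cancer <- function(recs) {
  recs %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      n_keys = dplyr::n(),
      n_positive = sum(.data$n_high + .data$n_medium + .data$n_low > 0),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_positive > 0) %>%
    dplyr::mutate(fraction = .data$n_positive / .data$n_keys) %>%
    dplyr::arrange(.data$fraction, .data$gene)
}

#' Build the enriched (rare) protein set from detection fractions
#'
#' A protein is "enriched" (cell-type specific, rarely detected) when its
#' detection fraction lies at or below the first quartile of the observed
#' fraction distribution. The quartile is computed with linear interpolation
#' between order statistics (the [stats::quantile()] default, type 7), and the
#' membership boundary is inclusive, so the set is reproducible bit-for-bit.
#' The cutoff is distribution-relative, not a fixed 0.25: with different
#' stringencies the distribution shifts and the set changes size with it.
#'
#' @param fractions A tibble from [detection_fractions()] (or a named numeric
#'   vector of fractions). At least 4 proteins are required for a meaningful
#'   quartile.
#' @param stringency Label stored on the returned set (informational).
#' @return An `enriched_set` object with elements `stringency`, `fractions`,
#'   `threshold` and `members`. Has [tidy()] and [glance()] methods.
#' @examples
#' fr <- detection_fractions(worked_example_fixture())
#' build_enriched_set(fr)
#' @export
build_enriched_set <- function(fractions, stringency = "normal") {
  if (is.numeric(fractions)) {
    fractions <- tibble::tibble(
      gene = if (is.null(names(fractions))) as.character(seq_along(fractions))
             else names(fractions),
      fraction = unname(fractions)
    )
  }
  require_columns(fractions, c("gene", "fraction"), "fraction table")
  if (nrow(fractions) < 4) {
    abort_cellstainr(
      paste0("need at least 4 proteins with a detection fraction to form a ",
             "quartile cutoff; got ", nrow(fractions)),
      "too_few_proteins"
    )
  }
  threshold <- quantile(fractions$fraction, 0.25, type = 7, names = FALSE)
  structure(
    list(
      stringency = stringency,
      fractions = tibble::as_tibble(fractions),
      threshold = threshold,
      members = fractions$gene[fractions$fraction <= threshold]
    ),
    class = "enriched_set"
  )
}

#' Enriched protein set straight from staining records
#'
#' Convenience wrapper: [detection_fractions()] followed by
#' [build_enriched_set()].
#'
#' @inheritParams detection_fractions
#' @return An `enriched_set` object.
#' @export
enriched_proteins <- function(records, stringency = "normal") {
  build_enriched_set(detection_fractions(records, stringency), stringency)
}

#' @export
print.enriched_set <- function(x, ...) {
  cat("<enriched protein set>\n")
  cat("  stringency: ", x$stringency, "\n", sep = "")
  cat("  proteins with a fraction: ", nrow(x$fractions), "\n", sep = "")
  cat("  first-quartile cutoff: ", format(x$threshold, digits = 4), "\n", sep = "")
  cat("  members (fraction <= cutoff): ", length(x$members), "\n", sep = "")
  invisible(x)
}
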