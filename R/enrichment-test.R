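# Per-cell-type over-representation test of enriched-and-detected proteins in
# the query, and the Holm step-down correction across cell types.

#' Build the 2x2 contingency table for one cell type
#'
#' The universe is the set of proteins evaluated in the cell type (after
#' stringency filtering and best-level deduplication). A protein is a
#' "success" when it belongs to the enriched set *and* stains positively in
#' this cell type; rows split the universe into query and non-query proteins.
#' Query proteins not evaluated in the cell type are excluded from all four
#' cells. With `background = "all"` the universe is instead every protein in
#' the filtered dataset, proteins unevaluated in the cell type counting as
#' not detected there.
#'
#' @param records A staining-record tibble.
#' @param key A display label as produced by [cell_type_key()], or a length-2
#'   character vector `c(tissue, cell_type)`.
#' @param query A query (string, tokens or [parse_query()] result).
#' @param enriched An `enriched_set` from [build_enriched_set()], or a
#'   character vector of member genes.
#' @param stringency Reliability stringency used to filter `records`.
#' @param background `"evaluated"` (default) or `"all"`; see above.
#' @return A 2x2 integer matrix with rows `in_query`/`not_in_query` and
#'   columns `enriched_detected`/`other`.
#' @export
build_contingency <- function(records, key, query, enriched,
                              stringency = "normal",
                              background = c("evaluated", "all")) {
  background <- match.arg(background)
  if (length(key) == 2) key <- cell_type_key(key[1], key[2])
  members <- if (inherits(enriched, "enriched_set")) enriched$members else enriched
  query <- as_query(query)
  dedup <- prepare_records(records, stringency)
  in_key <- dplyr::filter(dedup, .data$display == key)
  if (nrow(in_key) == 0) {
    abort_cellstainr(paste0("no protein evaluated in cell type: ", key), "empty_input")
  }
  tabulate_key(in_key, query$tokens, members,
               n_universe = length(unique(dedup$gene)),
               n_query_total = sum(query$tokens %in% dedup$gene),
               background = background)
}

tabulate_key <- function(in_key, tokens, members, n_universe, n_query_total,
                         background) {
  in_query <- in_key$gene %in% tokens
  success <- in_key$gene %in% members & in_key$weight > 0
  a <- sum(in_query & success)
  c_ <- sum(!in_query & success)
  if (background == "evaluated") {
    b <- sum(in_query & !success)
    d <- sum(!in_query & !success)
  } else {
    b <- n_query_total - a
    d <- n_universe - n_query_total - c_
  }
  matrix(as.integer(c(a, c_, b, d)), nrow = 2,
         dimnames = list(query = c("in_query", "not_in_query"),
                         protein = c("enriched_detected", "other")))
}

as_contingency <- function(tbl) {
  stopifnot(length(tbl) == 4, all(tbl >= 0))
  as.vector(tbl)  # a, c, b, d when a matrix; a, b, c, d when a plain vector
}

#' One-sided Fisher exact p-value for query enrichment
#'
#' The one-sided ("greater") p-value is the upper hypergeometric tail
#' P(X >= a) when drawing `a + b` proteins (the query margin) from a
#' population of `a + b + c + d` containing `a + c` successes. With
#' `alternative = "two.sided"` the usual two-sided Fisher exact p-value is
#' returned.
#'
#' @param tbl A 2x2 matrix as from [build_contingency()], or the four counts
#'   `c(a, b, c, d)` with `a` = query successes, `b` = query failures, `c` =
#'   background successes, `d` = background failures.
#' @param alternative `"greater"` (default, an enrichment claim) or
#'   `"two.sided"`.
#' @return A p-value in (0, 1].
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2))  # 17/70
#' @export
fisher_exact <- function(tbl, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  v <- if (is.matrix(tbl)) c(tbl[1, 1], tbl[1, 2], tbl[2, 1], tbl[2, 2])
       else as.numeric(tbl)
  a <- v[1]; b <- v[2]; c_ <- v[3]; d <- v[4]
  if (alternative == "greater") {
    phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(a, c_, b, d), nrow = 2),
                       alternative = "two.sided")$p.value
  }
}

#' Chi-squared p-value for a 2x2 staining contingency table
#'
#' Pearson's chi-squared test with continuity correction, one degree of
#' freedom. When any expected cell count is below 1 the statistic is
#' meaningless; the function then warns and returns 1.0 rather than a
#' spurious p-value.
#'
#' @inheritParams fisher_exact
#' @return A p-value in (0, 1].
#' @export
chi_square <- function(tbl) {
  v <- if (is.matrix(tbl)) c(tbl[1, 1], tbl[1, 2], tbl[2, 1], tbl[2, 2])
       else as.numeric(tbl)
  m <- matrix(c(v[1], v[3], v[2], v[4]), nrow = 2)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 1)) {
    warn("expected cell count below 1; chi-squared p-value set to 1",
         class = "cellstainr_warning_low_expected")
    return(1)
  }
  suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value)
}

#' Holm step-down adjustment of p-values
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by
#' `n - i + 1`, enforces the running maximum, caps at 1, and returns the
#' adjusted values in the original order.
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, elementwise >= the raw ones and <= 1.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.na(pvalues) & (pvalues <= 0 | pvalues > 1))) {
    abort_cellstainr("p-values must lie in (0, 1]", "invalid_pvalue")
  }
  p.adjust(pvalues, method = "holm")
}
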