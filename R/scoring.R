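# The staining score, the confidence score, and the ranked query result table.

#' Staining score of a cell type for a query
#'
#' With `t` query proteins tested in a cell type, of which `h` stained High,
#' `m` Medium and `l` Low, the staining score is
#' \deqn{(100 h + 50 m + 25 l) / t,}
#' a 0-100 scale that over-weights high-intensity staining. It is 100 exactly
#' when every tested protein stains High, and 0 when none stains at all.
#'
#' @param h,m,l Counts of proteins with High / Medium / Low staining.
#' @param t Total proteins tested in the cell type; must be >= 1.
#' @return The staining score, vectorized over the inputs.
#' @examples
#' staining_score(h = 3, m = 0, l = 0, t = 4)  # 75
#' staining_score(h = 0, m = 1, l = 0, t = 4)  # 12.5
#' @export
staining_score <- function(h, m, l, t) {
  if (any(t < 1)) {
    abort_cellstainr("staining score is undefined for t = 0 (no protein tested)",
                     "undefined_score")
  }
  (100 * h + 50 * m + 25 * l) / t
}

#' Confidence score: staining score down-weighted for small queries
#'
#' `min(p, 50) * s / 50`, where `p` is the number of query proteins tested and
#' `s` the staining score. The cap at 50 standardizes the range: the
#' confidence score equals the staining score whenever at least 50 proteins
#' were tested, and shrinks toward 0 for small lists, so rankings can weight
#' depth of evidence as well as staining intensity.
#'
#' @param p Number of proteins tested (>= 0).
#' @param s Staining score in \[0, 100\].
#' @return The confidence score, vectorized; always `<= s`.
#' @examples
#' confidence_score(p = 5, s = 57.75)   # 5.775
#' confidence_score(p = 50, s = 66.75)  # 66.75
#' @export
confidence_score <- function(p, s) {
  stopifnot(all(p >= 0), all(s >= 0), all(s <= 100))
  pmin(p, 50) * s / 50
}

#' Query a staining atlas with a gene list and rank cell types
#'
#' The main entry point. Matches the query symbols against the atlas's gene
#' names (case-insensitively), resolves duplicate records per gene and cell
#' type by best level wins, computes the staining score and confidence score
#' for every cell type where at least one query protein was tested, tests each
#' cell type for over-representation of enriched-and-detected proteins in the
#' query (one-sided Fisher exact by default), and Holm-adjusts the p-values
#' across all scored cell types. Results are sorted by staining score
#' descending, ties broken by more proteins tested, then by label, so the
#' table is fully deterministic.
#'
#' @param records A staining-record tibble, e.g. from [read_normal_tissue()],
#'   [generate_atlas()] or [worked_example_fixture()].
#' @param query Gene symbols: a free-text string, a character vector, or a
#'   [parse_query()] result.
#' @param stringency Reliability stringency (`"normal"`, `"low"`, `"high"`).
#' @param test `"fisher"` (default) or `"chisq"`.
#' @param alternative `"greater"` (default) or `"two.sided"` (Fisher only).
#' @param t_mode How the denominator `t` is counted: `"tested"` (default)
#'   counts only query proteins with a record in the cell type, so proteins
#'   absent from a cell type do not dilute its score; `"matched"` uses all
#'   matched query proteins everywhere, diluting sparsely annotated cell
#'   types.
#' @param background Universe for the contingency table: `"evaluated"`
#'   (proteins evaluated in the cell type, default) or `"all"` (every protein
#'   in the filtered dataset).
#' @param compute_pvalue Set `FALSE` to skip enrichment testing (faster; used
#'   by the permutation study).
#' @param show_proteins Include a `detected_proteins` column listing the
#'   positively stained query proteins and their levels.
#' @return A `stain_ranking` tibble with one row per scored cell type:
#'   `tissue`, `cell_type`, `cell_type_key`, the counts `n_tested`, `n_high`,
#'   `n_medium`, `n_low`, `n_not_detected`, `staining_score`,
#'   `confidence_score`, `n_enriched_detected`, `p_value`, `p_adjusted`, and
#'   optionally `detected_proteins`. Query metadata is retrievable with
#'   [glance()].
#' @examples
#' score_query(worked_example_fixture(), "PRSS1, PNLIP, CELA3A, PRL")
#' @export
score_query <- function(records, query,
                        stringency = c("normal", "low", "high"),
                        test = c("fisher", "chisq"),
                        alternative = c("greater", "two.sided"),
                        t_mode = c("tested", "matched"),
                        background = c("evaluated", "all"),
                        compute_pvalue = TRUE,
                        show_proteins = TRUE) {
  stringency <- match.arg(stringency)
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  t_mode <- match.arg(t_mode)
  background <- match.arg(background)
  query <- as_query(query)

  dedup <- prepare_records(records, stringency)
  atlas_genes <- unique(dedup$gene)
  matched <- intersect(query$tokens, atlas_genes)
  if (length(matched) == 0) {
    abort_cellstainr(
      paste0("none of the query symbols match a gene name in the atlas: ",
             paste(query$tokens, collapse = ", ")),
      "no_genes_matched"
    )
  }

  qrec <- dplyr::filter(dedup, .data$gene %in% matched)
  comp <- qrec %>%
    dplyr::group_by(.data$display) %>%
    dplyr::summarise(
      tissue = dplyr::first(.data$tissue),
      cell_type = dplyr::first(.data$cell_type),
      n_tested = dplyr::n(),
      n_high = sum(.data$level == "High"),
      n_medium = sum(.data$level == "Medium"),
      n_low = sum(.data$level == "Low"),
      detected_proteins = paste(
        sort(paste0(.data$gene, " (", .data$level, ")")[.data$weight > 0]),
        collapse = "; "
      ),
      .groups = "drop"
    )
  if (t_mode == "matched") comp$n_tested <- length(matched)
  comp <- comp %>%
    dplyr::mutate(
      n_not_detected = .data$n_tested - .data$n_high - .data$n_medium - .data$n_low,
      staining_score = staining_score(.data$n_high, .data$n_medium, .data$n_low,
                                      .data$n_tested),
      confidence_score = confidence_score(.data$n_tested, .data$staining_score)
    )

  comp <- dplyr::bind_cols(
    comp,
    enrichment_pvalues(dedup, comp$display, matched,
                       compute_pvalue = compute_pvalue, test = test,
                       alternative = alternative, background = background)
  )

  out <- comp %>%
    dplyr::arrange(dplyr::desc(.data$staining_score), dplyr::desc(.data$n_tested),
                   .data$display) %>%
    dplyr::select(
      "tissue", "cell_type", cell_type_key = "display",
      "n_tested", "n_high", "n_medium", "n_low", "n_not_detected",
      "staining_score", "confidence_score",
      "n_enriched_detected", "p_value", "p_adjusted",
      dplyr::any_of(if (show_proteins) "detected_proteins" else character(0))
    )
  new_stain_ranking(out, query = query, matched = matched,
                    stringency = stringency, test = test,
                    alternative = alternative, t_mode = t_mode,
                    background = background)
}

# Fisher/chi-squared p-values for each display key, Holm-adjusted across keys.
enrichment_pvalues <- function(dedup, keys, matched, compute_pvalue, test,
                               alternative, background) {
  empty <- tibble::tibble(
    n_enriched_detected = rep(NA_integer_, length(keys)),
    p_value = NA_real_, p_adjusted = NA_real_
  )
  if (!compute_pvalue) return(empty)
  fractions <- fractions_from_dedup(dedup)
  if (nrow(fractions) < 4) {
    warn(paste0("only ", nrow(fractions), " protein(s) ever stain positively; ",
                "enriched-protein p-values not computed"),
         class = "cellstainr_warning_no_enriched_set")
    return(empty)
  }
  members <- build_enriched_set(fractions)$members
  n_universe <- length(unique(dedup$gene))
  n_query_total <- length(matched)
  tables <- dedup %>%
    dplyr::filter(.data$display %in% keys) %>%
    dplyr::group_by(.data$display) %>%
    dplyr::group_map(function(g, k) {
      tbl <- tabulate_key(g, matched, members, n_universe, n_query_total,
                          background)
      tibble::tibble(display = k$display, a = tbl[1, 1],
                     p_value = if (test == "fisher") fisher_exact(tbl, alternative)
                               else chi_square(tbl))
    }) %>%
    dplyr::bind_rows()
  tables <- tables[match(keys, tables$display), ]
  tibble::tibble(
    n_enriched_detected = tables$a,
    p_value = tables$p_value,
    p_adjusted = holm_adjust(tables$p_value)
  )
}

new_stain_ranking <- function(tbl, ...) {
  structure(
    tbl,
    meta = list(...),
    class = c("stain_ranking", class(tibble::tibble()))
  )
}

normalize_cancer_records <- function(cancer_records) {
  require_columns(cancer_records,
                  c("gene_name", "cancer", "n_high", "n_medium", "n_low",
                    "n_not_detected"),
                  "cancer staining table")
  if (nrow(cancer_records) == 0) {
    abort_cellstainr("cancer staining table is empty", "empty_input")
  }
  tibble::as_tibble(cancer_records) %>%
    dplyr::mutate(
      gene = toupper(stringr::str_squish(.data$gene_name)),
      display = toupper(stringr::str_squish(.data$cancer)),
      n_patients = .data$n_high + .data$n_medium + .data$n_low +
        .data$n_not_detected
    ) %>%
    dplyr::filter(.data$n_patients > 0) %>%
    # collapse duplicate gene x cancer rows by summing patient counts
    dplyr::group_by(.data$gene, .data$display) %>%
    dplyr::summarise(
      cancer = dplyr::first(.data$cancer),
      dplyr::across(dplyr::all_of(c("n_high", "n_medium", "n_low",
                                    "n_not_detected", "n_patients")), sum),
      .groups = "drop"
    )
}

#' Query a cancer staining table with a gene list
#'
#' The cancer analogue of [score_query()]. Cancer records carry patient counts
#' per staining level rather than a single call, and samples of the same
#' cancer type can disagree; the counts are therefore converted to fractional
#' level contributions — for a gene with counts (high, medium, low, not
#' detected) out of N patients in a cancer, the cancer's `h` accumulates
#' high/N, `m` medium/N and `l` low/N — and the same staining-score equation
#' applies with `t` the number of matched genes with any patient in that
#' cancer. Enriched-protein p-values use "positive" = at least one patient
#' with High/Medium/Low staining; there is no reliability column, so no
#' stringency filter.
#'
#' @param cancer_records A cancer staining tibble, e.g. from [read_cancer()].
#' @inheritParams score_query
#' @return A `stain_ranking` tibble with one row per cancer: `cancer`,
#'   `cell_type_key`, `n_tested`, fractional `n_high`/`n_medium`/`n_low`/
#'   `n_not_detected`, `staining_score`, `confidence_score`,
#'   `n_enriched_detected`, `p_value`, `p_adjusted`, optionally
#'   `detected_proteins`.
#' @export
score_query_cancer <- function(cancer_records, query,
                               test = c("fisher", "chisq"),
                               alternative = c("greater", "two.sided"),
                               background = c("evaluated", "all"),
                               compute_pvalue = TRUE,
                               show_proteins = TRUE) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  background <- match.arg(background)
  query <- as_query(query)

  recs <- normalize_cancer_records(cancer_records)
  matched <- intersect(query$tokens, unique(recs$gene))
  if (length(matched) == 0) {
    abort_cellstainr(
      paste0("none of the query symbols match a gene name in the cancer table: ",
             paste(query$tokens, collapse = ", ")),
      "no_genes_matched"
    )
  }

  comp <- recs %>%
    dplyr::filter(.data$gene %in% matched) %>%
    dplyr::group_by(.data$display) %>%
    dplyr::summarise(
      cancer = dplyr::first(.data$cancer),
      n_tested = dplyr::n(),
      n_high = sum(.data$n_high / .data$n_patients),
      n_medium = sum(.data$n_medium / .data$n_patients),
      n_low = sum(.data$n_low / .data$n_patients),
      detected_proteins = paste(
        sort(paste0(.data$gene, " (",
                    .data$n_high + .data$n_medium + .data$n_low, "/",
                    .data$n_patients, " patients positive)")
             )[.data$n_high + .data$n_medium + .data$n_low > 0],
        collapse = "; "
      ),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      n_not_detected = .data$n_tested - .data$n_high - .data$n_medium - .data$n_low,
      staining_score = staining_score(.data$n_high, .data$n_medium, .data$n_low,
                                      .data$n_tested),
      confidence_score = confidence_score(.data$n_tested, .data$staining_score)
    )

  comp <- dplyr::bind_cols(
    comp,
    cancer_enrichment_pvalues(recs, comp$display, matched, compute_pvalue,
                              test, alternative, background)
  )

  out <- comp %>%
    dplyr::arrange(dplyr::desc(.data$staining_score), dplyr::desc(.data$n_tested),
                   .data$display) %>%
    dplyr::select(
      "cancer", cell_type_key = "display",
      "n_tested", "n_high", "n_medium", "n_low", "n_not_detected",
      "staining_score", "confidence_score",
      "n_enriched_detected", "p_value", "p_adjusted",
      dplyr::any_of(if (show_proteins) "detected_proteins" else character(0))
    )
  new_stain_ranking(out, query = query, matched = matched,
                    stringency = NA_character_, test = test,
                    alternative = alternative, t_mode = "tested",
                    background = background)
}

cancer_enrichment_pvalues <- function(recs, keys, matched, compute_pvalue,
                                      test, alternative, background) {
  empty <- tibble::tibble(
    n_enriched_detected = rep(NA_integer_, length(keys)),
    p_value = NA_real_, p_adjusted = NA_real_
  )
  if (!compute_pvalue) return(empty)
  fractions <- fractions_from_cancer(recs)
  if (nrow(fractions) < 4) {
    warn(paste0("only ", nrow(fractions), " protein(s) ever stain positively; ",
                "enriched-protein p-values not computed"),
         class = "cellstainr_warning_no_enriched_set")
    return(empty)
  }
  members <- build_enriched_set(fractions)$members
  n_universe <- length(unique(recs$gene))
  tables <- recs %>%
    dplyr::mutate(weight = as.numeric(.data$n_high + .data$n_medium +
                                        .data$n_low > 0)) %>%
    dplyr::filter(.data$display %in% keys) %>%
    dplyr::group_by(.data$display) %>%
    dplyr::group_map(function(g, k) {
      tbl <- tabulate_key(g, matched, members, n_universe, length(matched),
                          background)
      tibble::tibble(display = k$display, a = tbl[1, 1],
                     p_value = if (test == "fisher") fisher_exact(tbl, alternative)
                               else chi_square(tbl))
    }) %>%
    dplyr::bind_rows()
  tables <- tables[match(keys, tables$display), ]
  tibble::tibble(
    n_enriched_detected = tables$a,
    p_value = tables$p_value,
    p_adjusted = holm_adjust(tables$p_value)
  )
}
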