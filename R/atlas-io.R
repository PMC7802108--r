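# Readers and writers for the HPA-style staining-table dialects, plus the
# query-list parser. All readers return tibbles carrying a parse report as an
# attribute so pipelines can assert on what was dropped.

# required header -> canonical column name, matched case-insensitively
normal_tissue_columns <- c(
  "Gene" = "gene_id", "Gene name" = "gene_name", "Tissue" = "tissue",
  "Cell type" = "cell_type", "Level" = "level", "Reliability" = "reliability"
)
cancer_columns <- c(
  "Gene" = "gene_id", "Gene name" = "gene_name", "Cancer" = "cancer",
  "High" = "n_high", "Medium" = "n_medium", "Low" = "n_low",
  "Not detected" = "n_not_detected"
)

read_raw_tsv <- function(path, required) {
  if (!file.exists(path)) {
    abort_cellstainr(paste0("file does not exist: ", path), "io")
  }
  if (file.size(path) == 0) {
    abort_cellstainr(paste0("empty input file: ", path), "empty_input")
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  have <- tolower(stringr::str_squish(names(tbl)))
  idx <- match(tolower(names(required)), have)
  if (anyNA(idx)) {
    missing <- names(required)[is.na(idx)]
    abort_cellstainr(
      paste0("input is missing required column(s): ", paste(missing, collapse = ", ")),
      "schema"
    )
  }
  tbl <- tbl[idx]
  names(tbl) <- unname(required)
  if (nrow(tbl) == 0) {
    abort_cellstainr(paste0("no data rows in: ", path), "empty_input")
  }
  tbl
}

new_parse_report <- function(n_total, n_retained, dropped) {
  structure(
    c(list(n_total = n_total, n_retained = n_retained), dropped),
    class = "parse_report"
  )
}

#' @export
print.parse_report <- function(x, ...) {
  cat("<parse report>\n")
  cat("  data lines: ", x$n_total, "\n", sep = "")
  cat("  retained:   ", x$n_retained, "\n", sep = "")
  for (nm in setdiff(names(x), c("n_total", "n_retained"))) {
    cat("  ", nm, ": ", x[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Retrieve the parse report attached to a parsed table
#'
#' @param x A tibble returned by [read_normal_tissue()] or [read_cancer()].
#' @return A `parse_report` list with counts of total data lines, retained
#'   records, and records dropped per reason. Retained plus dropped always
#'   equals the total.
#' @export
parse_report <- function(x) {
  attr(x, "parse_report", exact = TRUE)
}

#' Read an HPA-style normal-tissue staining table
#'
#' Parses a tab-delimited staining table with columns `Gene`, `Gene name`,
#' `Tissue`, `Cell type`, `Level` and `Reliability` (order-insensitive,
#' case-insensitive header match) into one record per gene x tissue x cell type
#' observation. The staining level and reliability vocabularies are closed:
#' values are matched case-insensitively after trimming, and rows whose level
#' (e.g. `"N/A"`) or reliability falls outside the vocabulary, or whose gene
#' name is blank, are dropped and counted in the parse report rather than
#' erroring, since public atlas files do contain such rows.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene_id`, `gene_name`, `tissue`,
#'   `cell_type`, `level`, `reliability`, with a [parse_report()] attribute.
#' @seealso [read_cancer()], [write_atlas_tsv()]
#' @export
read_normal_tissue <- function(path) {
  tbl <- read_raw_tsv(path, normal_tissue_columns)
  n_total <- nrow(tbl)
  tbl$level <- normalize_vocab(tbl$level, stain_levels)
  tbl$reliability <- normalize_vocab(tbl$reliability, reliability_levels)
  bad_level <- is.na(tbl$level)
  bad_rel <- !bad_level & is.na(tbl$reliability)
  bad_gene <- !bad_level & !bad_rel & stringr::str_squish(tbl$gene_name) == ""
  keep <- !(bad_level | bad_rel | bad_gene)
  out <- tibble::as_tibble(tbl[keep, ])
  out$gene_name <- stringr::str_squish(out$gene_name)
  attr(out, "parse_report") <- new_parse_report(
    n_total, sum(keep),
    list(n_dropped_level = sum(bad_level), n_dropped_reliability = sum(bad_rel),
         n_dropped_gene = sum(bad_gene))
  )
  out
}

#' Read an HPA-style cancer (pathology) staining table
#'
#' Parses a tab-delimited table with columns `Gene`, `Gene name`, `Cancer`,
#' and per-level patient counts `High`, `Medium`, `Low`, `Not detected`.
#' Counts must be non-negative integers; a non-integer count is a parse error
#' citing the offending file line. Rows whose four counts are all blank, or
#' all zero, carry no staining information and are dropped and counted in the
#' parse report.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene_id`, `gene_name`, `cancer`, `n_high`,
#'   `n_medium`, `n_low`, `n_not_detected`, with a [parse_report()] attribute.
#' @export
read_cancer <- function(path) {
  tbl <- read_raw_tsv(path, cancer_columns)
  n_total <- nrow(tbl)
  count_cols <- c("n_high", "n_medium", "n_low", "n_not_detected")
  counts <- lapply(tbl[count_cols], stringr::str_squish)
  blank <- Reduce(`&`, lapply(counts, function(x) x == "" | is.na(x)))
  for (j in seq_along(count_cols)) {
    x <- counts[[j]]
    bad <- !blank & !(x == "" | is.na(x)) & !stringr::str_detect(x, "^[0-9]+$")
    if (any(bad)) {
      line <- which(bad)[1] + 1L  # header occupies file line 1
      abort_cellstainr(
        paste0("non-integer count '", x[which(bad)[1]], "' in column '",
               names(cancer_columns)[match(count_cols[j], cancer_columns)],
               "' at line ", line),
        "parse"
      )
    }
  }
  for (col in count_cols) {
    v <- stringr::str_squish(tbl[[col]])
    v[v == "" | is.na(v)] <- "0"
    tbl[[col]] <- as.integer(v)
  }
  all_zero <- !blank &
    tbl$n_high + tbl$n_medium + tbl$n_low + tbl$n_not_detected == 0L
  bad_gene <- !blank & !all_zero & stringr::str_squish(tbl$gene_name) == ""
  keep <- !(blank | all_zero | bad_gene)
  out <- tibble::as_tibble(tbl[keep, ])
  out$gene_name <- stringr::str_squish(out$gene_name)
  attr(out, "parse_report") <- new_parse_report(
    n_total, sum(keep),
    list(n_dropped_blank = sum(blank), n_dropped_zero = sum(all_zero),
         n_dropped_gene = sum(bad_gene))
  )
  out
}

#' Parse a free-text gene/protein query list
#'
#' Splits a query on any run of spaces, commas, tabs or newlines, upper-cases
#' the tokens, and de-duplicates them preserving first occurrence. Token order
#' never affects downstream scores.
#'
#' @param raw A string, or a character vector of tokens.
#' @return A `query_list` object with elements `raw`, `tokens` and `n_unique`.
#' @examples
#' parse_query("PRSS1, PNLIP CELA3A\nPRL")
#' @export
parse_query <- function(raw) {
  if (is.null(raw)) abort_cellstainr("query must not be NULL", "empty_query")
  joined <- paste(as.character(raw), collapse = " ")
  tokens <- stringr::str_split_1(joined, "[,\\s]+")
  tokens <- unique(toupper(tokens[tokens != ""]))
  if (length(tokens) == 0) {
    abort_cellstainr("query contains no gene symbols after splitting", "empty_query")
  }
  structure(
    list(raw = raw, tokens = tokens, n_unique = length(tokens)),
    class = "query_list"
  )
}

#' @export
print.query_list <- function(x, ...) {
  cat("<query of ", x$n_unique, " unique symbol(s)>\n", sep = "")
  cat(" ", paste(x$tokens, collapse = ", "), "\n")
  invisible(x)
}

as_query <- function(x) {
  if (inherits(x, "query_list")) x else parse_query(x)
}

#' Write a result table to CSV
#'
#' Writes an RFC-4180-style CSV with a header row. Score and percentage
#' columns (`staining_score`, `confidence_score`, `pct_stained`) are rendered
#' with exactly two decimal places; p-values keep full precision. The decimal
#' separator is always `"."` and the delimiter always `","`, independent of
#' locale. Re-reading the file reproduces the table (scores to two decimals).
#'
#' @param results A non-empty data frame, e.g. from [score_query()] or
#'   [summarize_atlas()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort_cellstainr("results must be a non-empty data frame", "empty_input")
  }
  out <- tibble::as_tibble(results)
  for (col in intersect(c("staining_score", "confidence_score", "pct_stained"),
                        names(out))) {
    out[[col]] <- sprintf("%.2f", out[[col]])
  }
  tryCatch(
    readr::write_csv(out, path, progress = FALSE),
    error = function(e) {
      abort_cellstainr(paste0("cannot write results to ", path, ": ",
                              conditionMessage(e)), "io")
    }
  )
  invisible(path)
}
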