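# Empirical null distributions of the staining score from random gene lists.

#' Null staining-score distributions from random gene lists
#'
#' Repeatedly samples gene lists uniformly without replacement from the
#' distinct gene symbols of the (stringency-filtered) atlas, scores every cell
#' type for each list, and records the full score vector plus the top-`top_k`
#' ranks per run. Scoring uses a precomputed gene-by-cell-type weight matrix,
#' which is arithmetically identical to [score_query()] without p-values but
#' fast enough for thousands of runs.
#'
#' Each (list size, run) pair gets its own RNG substream derived from `seed`,
#' so any subset of the study is reproducible independently of the rest.
#'
#' @param records A staining-record tibble.
#' @param n_runs Random lists per size (1000 reproduces the full study; 100 is
#'   a quick profile).
#' @param list_sizes Gene-list sizes to draw; each must not exceed the number
#'   of distinct genes in the (filtered) atlas.
#' @param top_k How many top-ranked cell types to flag per run.
#' @param seed Integer seed for the whole study.
#' @param stringency Reliability stringency applied before sampling; the
#'   sampling frame is the filtered atlas unless `frame = "all"`.
#' @param frame `"filtered"` (sample from genes surviving the stringency
#'   filter, default) or `"all"` (sample from every gene in `records`).
#' @return A `stain_null` tibble with one row per run x scored cell type:
#'   `list_size`, `run`, `cell_type_key`, `n_tested`, `staining_score`,
#'   `rank`, `in_top_k`.
#' @seealso [summarize_null()], [autoplot.stain_null()]
#' @export
run_permutations <- function(records, n_runs = 1000,
                             list_sizes = c(10, 25, 50, 100), top_k = 10,
                             seed = 1, stringency = "normal",
                             frame = c("filtered", "all")) {
  frame <- match.arg(frame)
  stopifnot(n_runs >= 1, top_k >= 1, all(list_sizes >= 1))
  normalized <- normalize_records(records)
  dedup <- if (frame == "filtered") {
    dedup_best_level(filter_stringency(normalized, stringency))
  } else {
    dedup_best_level(normalized)
  }
  genes <- sort(unique(dedup$gene))
  keys <- sort(unique(dedup$display))
  if (max(list_sizes) > length(genes)) {
    abort_cellstainr(
      paste0("largest list size (", max(list_sizes), ") exceeds the ",
             length(genes), " distinct genes in the sampling frame"),
      "config"
    )
  }
  # gene x key weight matrix; NA where the gene was not evaluated in the key
  w <- matrix(NA_real_, length(genes), length(keys),
              dimnames = list(genes, keys))
  w[cbind(match(dedup$gene, genes), match(dedup$display, keys))] <- dedup$weight

  out <- vector("list", length(list_sizes) * n_runs)
  i <- 0L
  for (size in list_sizes) {
    for (run in seq_len(n_runs)) {
      set.seed((seed + 1009L * size + run) %% .Machine$integer.max)
      sub <- w[sample.int(length(genes), size), , drop = FALSE]
      t_vec <- colSums(!is.na(sub))
      scored <- t_vec >= 1
      score <- colSums(sub, na.rm = TRUE)[scored] / t_vec[scored]
      rk <- rank(-score, ties.method = "first")
      i <- i + 1L
      out[[i]] <- tibble::tibble(
        list_size = size, run = run, cell_type_key = names(score),
        n_tested = unname(t_vec[scored]), staining_score = unname(score),
        rank = rk, in_top_k = rk <= top_k
      )
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("stain_null", class(res))
  attr(res, "config") <- list(n_runs = n_runs, list_sizes = list_sizes,
                              top_k = top_k, seed = seed,
                              stringency = stringency, frame = frame)
  res
}

#' Moment and quantile summary of a score distribution
#'
#' @param scores Numeric vector of staining scores (e.g. one list size's
#'   `staining_score` column from [run_permutations()]).
#' @return One-row tibble: `n`, `mean`, `sd`, `min`, `q25`, `median`, `q75`,
#'   `max`, `skewness` (moment skewness; 0 for a constant vector).
#' @export
summarize_null <- function(scores) {
  if (length(scores) == 0) abort_cellstainr("no scores to summarize", "empty_input")
  m <- mean(scores)
  m2 <- mean((scores - m)^2)
  skew <- if (m2 == 0) 0 else mean((scores - m)^3) / m2^1.5
  q <- quantile(scores, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  tibble::tibble(
    n = length(scores), mean = m, sd = sd(scores),
    min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5],
    skewness = skew
  )
}
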