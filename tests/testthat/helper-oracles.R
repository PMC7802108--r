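# Independent brute-force oracles and tiny record builders used across the
# suite. The oracles deliberately avoid the code paths they check.

# one staining record per call; defaults keep fixtures terse
rec <- function(gene, tissue, cell, level, rel = "Supported",
                id = paste0("ID_", gene)) {
  tibble::tibble(gene_id = id, gene_name = gene, tissue = tissue,
                 cell_type = cell, level = level, reliability = rel)
}

recs <- function(...) dplyr::bind_rows(...)

# Brute-force scoring: enumerate (key, protein, level) triples, resolve
# duplicates by best level with an explicit ordering, apply the score
# equation directly. Returns a data.frame keyed by display label.
brute_force_scores <- function(records, tokens, admitted = NULL) {
  tokens <- unique(toupper(tokens))
  if (!is.null(admitted)) records <- records[records$reliability %in% admitted, ]
  ord <- c("Not detected" = 0, "Low" = 1, "Medium" = 2, "High" = 3)
  key <- paste0(toupper(trimws(records$tissue)), " - ", trimws(records$cell_type))
  out <- list()
  for (k in sort(unique(key))) {
    h <- m <- l <- t <- 0
    for (g in tokens) {
      lv <- records$level[key == k & toupper(records$gene_name) == g]
      if (length(lv) == 0) next
      best <- lv[which.max(ord[lv])]
      t <- t + 1
      if (best == "High") h <- h + 1
      if (best == "Medium") m <- m + 1
      if (best == "Low") l <- l + 1
    }
    if (t >= 1) {
      out[[k]] <- data.frame(key = k, t = t,
                             score = (100 * h + 50 * m + 25 * l) / t)
    }
  }
  do.call(rbind, out)
}

# Hypergeometric tail by explicit enumeration with choose(); independent of
# phyper.
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  succ <- a + c
  draws <- a + b
  xs <- a:min(draws, succ)
  sum(choose(succ, xs) * choose(n - succ, draws - xs)) / choose(n, draws)
}

# drop the parse-report attribute so round-trip comparisons see only data
strip_report <- function(x) {
  attr(x, "parse_report") <- NULL
  x
}

# Hand-stepped Holm: sort ascending, multiply the i-th by (n - i + 1),
# running max, cap at 1, original order.
holm_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- pmin(1, cummax(p[ord] * (n - seq_len(n) + 1)))
  adj[order(ord)]
}
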