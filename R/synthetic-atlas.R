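# Synthetic staining atlases with controllable structure, so every part of
# the pipeline is testable without downloading atlas data.

#' Specify a synthetic staining atlas
#'
#' Describes an atlas of `n_tissues * cells_per_tissue` cell types and
#' `n_genes` genes. Each gene is evaluated in each cell type with probability
#' `coverage_probability`; evaluated records draw their staining level from
#' `level_probabilities` and their reliability from
#' `reliability_probabilities`. Passing a `cell_classes` table instead assigns
#' every cell type to a class with its own coverage and level distribution,
#' which creates the coverage/positivity heterogeneity seen in real atlases
#' (deeply annotated, broadly staining cell types next to sparsely annotated,
#' rarely staining ones). `marker_blocks` plants known marker structure: each
#' block is a `list(genes =, tissue =, cell_type =, level =)` whose records
#' appear verbatim in the output.
#'
#' @param n_tissues,cells_per_tissue,n_genes Positive counts.
#' @param level_probabilities Named probability vector over
#'   `High`/`Medium`/`Low`/`Not detected`; must sum to 1.
#' @param reliability_probabilities Named probability vector over
#'   `Enhanced`/`Supported`/`Approved`/`Uncertain`; must sum to 1.
#' @param coverage_probability Probability a gene is evaluated in a cell type.
#' @param cell_classes Optional data frame with columns `class`, `weight`,
#'   `coverage`, `p_high`, `p_medium`, `p_low`, `p_not_detected`; overrides
#'   `coverage_probability` and `level_probabilities` per cell type.
#' @param marker_blocks Optional list of marker blocks (see above).
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return An `atlas_spec` list.
#' @seealso [generate_atlas()], [heterogeneous_atlas_spec()]
#' @export
atlas_spec <- function(n_tissues = 20, cells_per_tissue = 5, n_genes = 600,
                       level_probabilities = c(High = 0.12, Medium = 0.18,
                                               Low = 0.20, `Not detected` = 0.50),
                       reliability_probabilities = c(Enhanced = 0.15,
                                                     Supported = 0.35,
                                                     Approved = 0.35,
                                                     Uncertain = 0.15),
                       coverage_probability = 0.6,
                       cell_classes = NULL, marker_blocks = NULL, seed = 1) {
  stopifnot(n_tissues >= 1, cells_per_tissue >= 1, n_genes >= 1,
            coverage_probability >= 0, coverage_probability <= 1)
  check_probs <- function(p, nms, what) {
    if (!setequal(names(p), nms) || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      abort_cellstainr(paste0(what, " must be a probability vector over ",
                              paste(nms, collapse = ", ")), "spec")
    }
  }
  check_probs(level_probabilities, stain_levels, "level_probabilities")
  check_probs(reliability_probabilities, reliability_levels,
              "reliability_probabilities")
  if (!is.null(cell_classes)) {
    require_columns(cell_classes,
                    c("class", "weight", "coverage", "p_high", "p_medium",
                      "p_low", "p_not_detected"), "cell_classes")
    rows <- cell_classes$p_high + cell_classes$p_medium + cell_classes$p_low +
      cell_classes$p_not_detected
    if (any(abs(rows - 1) > 1e-8)) {
      abort_cellstainr("cell_classes level probabilities must sum to 1 per row",
                       "spec")
    }
  }
  structure(
    list(n_tissues = n_tissues, cells_per_tissue = cells_per_tissue,
         n_genes = n_genes, level_probabilities = level_probabilities,
         reliability_probabilities = reliability_probabilities,
         coverage_probability = coverage_probability,
         cell_classes = cell_classes, marker_blocks = marker_blocks,
         seed = seed),
    class = "atlas_spec"
  )
}

#' Heterogeneous atlas specification for null-distribution studies
#'
#' A two-class atlas: half the cell types are deeply annotated and broadly
#' staining ("hot": coverage 0.9, positive levels common), half are sparsely
#' annotated and rarely staining ("cold": coverage 0.03, mostly not
#' detected). Because sparsely covered cell types only enter a query's result
#' table when a sampled list happens to hit them, small random lists
#' over-represent the hot, high-scoring cell types — which reproduces the
#' empirical behaviour that the staining-score null distribution shifts down
#' as the gene-list size grows.
#'
#' @inheritParams atlas_spec
#' @param ... Passed on to [atlas_spec()].
#' @return An `atlas_spec` with a two-class `cell_classes` table.
#' @export
heterogeneous_atlas_spec <- function(n_tissues = 20, cells_per_tissue = 5,
                                     n_genes = 600, seed = 1, ...) {
  classes <- tibble::tibble(
    class = c("hot", "cold"),
    weight = c(0.5, 0.5),
    coverage = c(0.90, 0.03),
    p_high = c(0.30, 0.02),
    p_medium = c(0.30, 0.05),
    p_low = c(0.20, 0.08),
    p_not_detected = c(0.20, 0.85)
  )
  atlas_spec(n_tissues = n_tissues, cells_per_tissue = cells_per_tissue,
             n_genes = n_genes, cell_classes = classes, seed = seed, ...)
}

#' Generate a synthetic normal-tissue staining atlas
#'
#' Draws an atlas from an [atlas_spec()]: deterministic given the spec's seed,
#' marker blocks appear verbatim, and the output satisfies every
#' staining-record invariant, so it round-trips losslessly through
#' [write_atlas_tsv()] and [read_normal_tissue()].
#'
#' @param spec An [atlas_spec()].
#' @return A staining-record tibble (`gene_id`, `gene_name`, `tissue`,
#'   `cell_type`, `level`, `reliability`).
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_spec"))
  set.seed(spec$seed)
  keys <- tidyr::expand_grid(
    tissue = sprintf("tissue %02d", seq_len(spec$n_tissues)),
    cell_type = sprintf("cell type %02d", seq_len(spec$cells_per_tissue))
  )
  n_keys <- nrow(keys)
  if (is.null(spec$cell_classes)) {
    keys$coverage <- spec$coverage_probability
    lv <- matrix(rep(unname(spec$level_probabilities[stain_levels]), each = n_keys),
                 nrow = n_keys)
  } else {
    cls <- spec$cell_classes
    idx <- sample.int(nrow(cls), n_keys, replace = TRUE,
                      prob = cls$weight / sum(cls$weight))
    keys$coverage <- cls$coverage[idx]
    lv <- cbind(cls$p_high[idx], cls$p_medium[idx], cls$p_low[idx],
                cls$p_not_detected[idx])
  }
  genes <- tibble::tibble(
    gene_name = sprintf("GENE%04d", seq_len(spec$n_genes)),
    gene_id = sprintf("SYNG%011d", seq_len(spec$n_genes))
  )

  per_key <- function(k) {
    evaluated <- runif(spec$n_genes) < keys$coverage[k]
    n <- sum(evaluated)
    if (n == 0) return(NULL)
    tibble::tibble(
      gene_id = genes$gene_id[evaluated],
      gene_name = genes$gene_name[evaluated],
      tissue = keys$tissue[k],
      cell_type = keys$cell_type[k],
      level = sample(stain_levels, n, replace = TRUE, prob = lv[k, ]),
      reliability = sample(reliability_levels, n, replace = TRUE,
                           prob = unname(spec$reliability_probabilities[reliability_levels]))
    )
  }
  records <- dplyr::bind_rows(lapply(seq_len(n_keys), per_key))

  if (!is.null(spec$marker_blocks)) {
    records <- apply_marker_blocks(records, spec$marker_blocks, keys, genes)
  }
  records
}

apply_marker_blocks <- function(records, blocks, keys, genes) {
  for (blk in blocks) {
    if (!all(c("genes", "tissue", "cell_type", "level") %in% names(blk))) {
      abort_cellstainr("marker block needs elements genes, tissue, cell_type, level",
                       "spec")
    }
    known <- any(tolower(keys$tissue) == tolower(blk$tissue) &
                   tolower(keys$cell_type) == tolower(blk$cell_type))
    if (!known) {
      abort_cellstainr(
        paste0("marker block references unknown cell type: ",
               cell_type_key(blk$tissue, blk$cell_type)),
        "spec"
      )
    }
    ids <- genes$gene_id[match(blk$genes, genes$gene_name)]
    ids[is.na(ids)] <- paste0("SYNMRK", seq_len(sum(is.na(ids))))
    forced <- tibble::tibble(
      gene_id = ids, gene_name = blk$genes,
      tissue = blk$tissue, cell_type = blk$cell_type,
      level = blk$level,
      reliability = blk$reliability %||% "Supported"
    )
    records <- records %>%
      dplyr::anti_join(forced, by = c("gene_name", "tissue", "cell_type")) %>%
      dplyr::bind_rows(forced)
  }
  records
}

#' Generate a synthetic cancer staining table
#'
#' Per gene x cancer pair (evaluated with probability `coverage_probability`),
#' draws `n_patients` patients into the four staining levels from
#' `level_probabilities`.
#'
#' @param n_cancers,n_genes,n_patients Positive counts.
#' @param level_probabilities Named probability vector over the four levels.
#' @param coverage_probability Probability a gene is evaluated in a cancer.
#' @param seed Integer seed.
#' @return A cancer staining tibble (`gene_id`, `gene_name`, `cancer`,
#'   `n_high`, `n_medium`, `n_low`, `n_not_detected`).
#' @export
generate_cancer_atlas <- function(n_cancers = 15, n_genes = 300,
                                  n_patients = 12,
                                  level_probabilities = c(High = 0.10,
                                                          Medium = 0.15,
                                                          Low = 0.20,
                                                          `Not detected` = 0.55),
                                  coverage_probability = 0.7, seed = 1) {
  stopifnot(abs(sum(level_probabilities) - 1) < 1e-8)
  set.seed(seed)
  grid <- tidyr::expand_grid(
    gene_idx = seq_len(n_genes),
    cancer = sprintf("cancer %02d", seq_len(n_cancers))
  ) %>%
    dplyr::filter(runif(dplyr::n()) < coverage_probability)
  counts <- t(rmultinom(nrow(grid), n_patients,
                        unname(level_probabilities[stain_levels])))
  tibble::tibble(
    gene_id = sprintf("SYNG%011d", grid$gene_idx),
    gene_name = sprintf("GENE%04d", grid$gene_idx),
    cancer = grid$cancer,
    n_high = counts[, 1], n_medium = counts[, 2], n_low = counts[, 3],
    n_not_detected = counts[, 4]
  )
}

#' The canonical pancreatic-enzyme worked example
#'
#' A minimal atlas encoding the textbook query of the pancreatic enzymes
#' PRSS1, PNLIP and CELA3A together with prolactin (PRL): the three enzymes
#' stain High in pancreatic exocrine glandular cells (PRL not detected), PRL
#' stains High in the anterior pituitary, and PRSS1 stains Medium in
#' intestinal glandular cells. Cells the description leaves unstated are
#' filled with `Not detected`, so all four proteins are evaluated in each of
#' the three named cell types — the only completion consistent with the
#' expected staining scores of 75, 25 and 12.5. Six distractor cell types
#' where all four proteins are not detected are included, and every record is
#' `Supported` so the fixture survives all stringency levels.
#'
#' @return A staining-record tibble.
#' @examples
#' score_query(worked_example_fixture(), "PRSS1, PNLIP, CELA3A, PRL")
#' @export
worked_example_fixture <- function() {
  genes <- c(PRSS1 = "SYNWE00001", PNLIP = "SYNWE00002",
             CELA3A = "SYNWE00003", PRL = "SYNWE00004")
  keys <- tibble::tribble(
    ~tissue, ~cell_type,
    "pancreas", "exocrine glandular cells",
    "pituitary gland", "cells in anterior",
    "small intestine", "glandular cells",
    "liver", "hepatocytes",
    "lung", "pneumocytes",
    "kidney", "cells in tubules",
    "skin", "keratinocytes",
    "testis", "leydig cells",
    "heart muscle", "myocytes"
  )
  records <- tidyr::expand_grid(gene_name = names(genes), keys) %>%
    dplyr::mutate(
      gene_id = unname(genes[.data$gene_name]),
      level = "Not detected",
      reliability = "Supported"
    )
  set_level <- function(df, gene, tissue, level) {
    df$level[df$gene_name == gene & df$tissue == tissue] <- level
    df
  }
  records %>%
    set_level("PRSS1", "pancreas", "High") %>%
    set_level("PNLIP", "pancreas", "High") %>%
    set_level("CELA3A", "pancreas", "High") %>%
    set_level("PRL", "pituitary gland", "High") %>%
    set_level("PRSS1", "small intestine", "Medium") %>%
    dplyr::select("gene_id", "gene_name", "tissue", "cell_type", "level",
                  "reliability")
}

#' Write staining records as an HPA-dialect TSV
#'
#' @param records A staining-record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_atlas_tsv <- function(records, path) {
  require_columns(records, unname(normal_tissue_columns), "staining-record table")
  out <- records[unname(normal_tissue_columns)]
  names(out) <- names(normal_tissue_columns)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write cancer staining records as an HPA-dialect TSV
#'
#' @param cancer_records A cancer staining tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cancer_tsv <- function(cancer_records, path) {
  require_columns(cancer_records, unname(cancer_columns), "cancer staining table")
  out <- cancer_records[unname(cancer_columns)]
  names(out) <- names(cancer_columns)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
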