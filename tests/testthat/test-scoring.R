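# Staining score, confidence score, and the ranked query table.

test_that("the staining score equation evaluates directly", {
  expect_equal(staining_score(h = 3, m = 0, l = 0, t = 4), 75)
  expect_equal(staining_score(h = 0, m = 1, l = 0, t = 4), 12.5)
  expect_equal(staining_score(h = 1, m = 1, l = 1, t = 3), 175 / 3)
  expect_equal(staining_score(h = 0, m = 0, l = 0, t = 5), 0)
  expect_equal(staining_score(h = 4, m = 0, l = 0, t = 4), 100)
  expect_error(staining_score(0, 0, 0, 0),
               class = "cellstainr_error_undefined_score")
})

test_that("the confidence score caps the tested-protein count at 50", {
  expect_equal(confidence_score(p = 5, s = 57.75), 5.775)
  expect_equal(confidence_score(p = 16, s = 42.5), 13.6)
  expect_equal(confidence_score(p = 50, s = 66.75), 66.75)
  expect_equal(confidence_score(p = 3, s = 50), 3)
  expect_equal(confidence_score(p = 120, s = 40), 40)
  expect_equal(confidence_score(p = 0, s = 80), 0)
  # never exceeds the staining score; equal iff p >= 50 or s = 0
  set.seed(1)
  p <- sample(0:120, 200, replace = TRUE)
  s <- runif(200, 0, 100)
  cs <- confidence_score(p, s)
  expect_true(all(cs <= s + 1e-12))
  expect_equal(abs(cs - s) < 1e-12, p >= 50 | s == 0)
})

test_that("the worked example ranks pancreas, pituitary, intestine", {
  res <- score_query(worked_example_fixture(), "PRSS1, PNLIP, CELA3A\nPRL")
  expect_equal(res$cell_type_key[1:3],
               c("PANCREAS - exocrine glandular cells",
                 "PITUITARY GLAND - cells in anterior",
                 "SMALL INTESTINE - glandular cells"))
  expect_equal(res$staining_score[1:3], c(75, 25, 12.5))
  expect_true(all(res$staining_score[-(1:3)] == 0))
  expect_true(all(res$n_tested == 4))
  # detected proteins are listed with their levels
  expect_match(res$detected_proteins[1], "PRSS1 \\(High\\)")
  expect_match(res$detected_proteins[3], "PRSS1 \\(Medium\\)")
  expect_equal(res$detected_proteins[1], "CELA3A (High); PNLIP (High); PRSS1 (High)")
})

test_that("a single uniquely staining gene scores 100 in its cell type", {
  records <- recs(
    rec("MARKER", "brain", "neurons", "High"),
    rec("MARKER", "liver", "hepatocytes", "Not detected"),
    rec("MARKER", "lung", "pneumocytes", "Not detected")
  )
  res <- score_query(records, "marker", compute_pvalue = FALSE)
  expect_equal(res$staining_score[res$cell_type_key == "BRAIN - neurons"], 100)
  expect_true(all(res$staining_score[res$cell_type_key != "BRAIN - neurons"] == 0))
})

test_that("query token order never changes the result", {
  atlas <- generate_atlas(atlas_spec(n_tissues = 5, cells_per_tissue = 2,
                                     n_genes = 60, seed = 5))
  genes <- unique(atlas$gene_name)[1:12]
  base <- score_query(atlas, genes)
  set.seed(9)
  for (i in 1:3) {
    perm <- score_query(atlas, sample(genes))
    expect_equal(tidy(perm), tidy(base))
  }
})

test_that("duplicate records resolve to the best level without double counting", {
  records <- recs(
    rec("A", "lung", "pneumocytes", "Low"),
    rec("A", "lung", "pneumocytes", "High"),   # second antibody, stronger
    rec("B", "lung", "pneumocytes", "Medium")
  )
  res <- score_query(records, c("A", "B"), compute_pvalue = FALSE)
  expect_equal(res$n_tested, 2)
  expect_equal(res$n_high, 1)
  expect_equal(res$n_medium, 1)
  expect_equal(res$staining_score, 75)
  # duplicating every record changes nothing
  res2 <- score_query(dplyr::bind_rows(records, records), c("A", "B"),
                      compute_pvalue = FALSE)
  expect_equal(tidy(res2), tidy(res))
})

test_that("scores match the brute-force oracle on random atlases", {
  for (seed in 1:4) {
    atlas <- generate_atlas(atlas_spec(n_tissues = 4, cells_per_tissue = 2,
                                       n_genes = 30,
                                       coverage_probability = 0.7, seed = seed))
    set.seed(seed + 100)
    tokens <- sample(unique(atlas$gene_name), 8)
    res <- score_query(atlas, tokens, stringency = "normal",
                       compute_pvalue = FALSE)
    oracle <- brute_force_scores(atlas, tokens,
                                 admitted = stringency_reliabilities("normal"))
    expect_setequal(res$cell_type_key, oracle$key)
    idx <- match(res$cell_type_key, oracle$key)
    expect_equal(res$staining_score, oracle$score[idx])
    expect_equal(res$n_tested, oracle$t[idx])
  }
})

test_that("upgrading one protein's level never lowers a score", {
  ladder <- c("Not detected", "Low", "Medium", "High")
  base <- recs(
    rec("A", "t", "c", "Low"),
    rec("B", "t", "c", "Medium"),
    rec("C", "t", "c", "Not detected")
  )
  for (from in 1:3) {
    lo <- base
    lo$level[lo$gene_name == "C"] <- ladder[from]
    hi <- base
    hi$level[hi$gene_name == "C"] <- ladder[from + 1]
    s_lo <- score_query(lo, c("A", "B", "C"), compute_pvalue = FALSE)$staining_score
    s_hi <- score_query(hi, c("A", "B", "C"), compute_pvalue = FALSE)$staining_score
    expect_gte(s_hi, s_lo)
  }
})

test_that("score bounds and attainment hold on generated atlases", {
  for (seed in 1:3) {
    atlas <- generate_atlas(atlas_spec(n_tissues = 5, cells_per_tissue = 2,
                                       n_genes = 50, seed = seed))
    set.seed(seed)
    res <- score_query(atlas, sample(unique(atlas$gene_name), 10),
                       compute_pvalue = FALSE)
    expect_true(all(res$staining_score >= 0 & res$staining_score <= 100))
    expect_equal(res$staining_score == 100, res$n_high == res$n_tested)
    expect_equal(res$staining_score == 0,
                 res$n_high + res$n_medium + res$n_low == 0)
    expect_true(all(res$confidence_score <= res$staining_score + 1e-12))
    # deterministic ordering: score desc, then t desc, then label
    expect_false(is.unsorted(-res$staining_score))
  }
})

test_that("unmatched queries fail with the offending tokens named", {
  expect_error(score_query(worked_example_fixture(), "NOSUCHGENE OTHER"),
               "NOSUCHGENE", class = "cellstainr_error_no_genes_matched")
})

test_that("t_mode 'matched' dilutes sparsely annotated cell types", {
  records <- recs(
    rec("A", "t1", "c", "High"),
    rec("B", "t1", "c", "High"),
    rec("A", "t2", "c", "High")  # B not evaluated in t2
  )
  tested <- score_query(records, c("A", "B"), compute_pvalue = FALSE)
  expect_equal(tested$staining_score[tested$cell_type_key == "T2 - c"], 100)
  matched <- score_query(records, c("A", "B"), t_mode = "matched",
                         compute_pvalue = FALSE)
  expect_equal(matched$staining_score[matched$cell_type_key == "T2 - c"], 50)
  expect_true(all(matched$n_tested == 2))
})

test_that("cancer patient counts contribute fractional levels", {
  cancer1 <- tibble::tibble(
    gene_id = "E1", gene_name = "A", cancer = "cancer X",
    n_high = 4L, n_medium = 0L, n_low = 0L, n_not_detected = 0L
  )
  res1 <- score_query_cancer(cancer1, "A", compute_pvalue = FALSE)
  expect_equal(res1$staining_score, 100)

  cancer2 <- cancer1
  cancer2$n_high <- 2L
  cancer2$n_medium <- 2L
  res2 <- score_query_cancer(cancer2, "A", compute_pvalue = FALSE)
  expect_equal(res2$staining_score, 75)
  expect_equal(res2$n_high, 0.5)
  expect_equal(res2$n_medium, 0.5)

  cancer3 <- dplyr::bind_rows(
    cancer1,
    tibble::tibble(gene_id = "E2", gene_name = "B", cancer = "cancer X",
                   n_high = 0L, n_medium = 0L, n_low = 0L, n_not_detected = 4L)
  )
  res3 <- score_query_cancer(cancer3, c("A", "B"), compute_pvalue = FALSE)
  expect_equal(res3$staining_score, 50)
  expect_equal(res3$n_tested, 2)
})

test_that("glance summarizes a ranking in one row", {
  res <- score_query(worked_example_fixture(), "PRSS1 PNLIP CELA3A PRL")
  gl <- glance(res)
  expect_equal(gl$n_query, 4)
  expect_equal(gl$n_matched, 4)
  expect_equal(gl$n_cell_types, 9)
  expect_equal(gl$top_cell_type, "PANCREAS - exocrine glandular cells")
  expect_equal(gl$top_staining_score, 75)
  expect_equal(gl$stringency, "normal")
})
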