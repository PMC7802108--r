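# Readers, writers and query parsing.

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

normal_header <- "Gene\tGene name\tTissue\tCell type\tLevel\tReliability"

test_that("normal-tissue parsing retains clean rows and counts dropped ones", {
  path <- write_tsv_fixture(c(
    normal_header,
    "ENSG1\tTP53\tlung\tpneumocytes\tHigh\tEnhanced",
    "ENSG1\tTP53\tliver\thepatocytes\tMedium\tSupported",
    "ENSG2\tALB\tliver\thepatocytes\tLow\tApproved",
    "ENSG2\tALB\tlung\tpneumocytes\tNot detected\tUncertain"
  ))
  tbl <- read_normal_tissue(path)
  expect_equal(nrow(tbl), 4)
  expect_setequal(names(tbl), c("gene_id", "gene_name", "tissue", "cell_type",
                                "level", "reliability"))
  rep <- parse_report(tbl)
  expect_equal(rep$n_total, 4)
  expect_equal(rep$n_retained, 4)
  expect_equal(rep$n_dropped_level, 0)

  # a level outside the closed vocabulary is dropped, not errored
  path2 <- write_tsv_fixture(c(
    normal_header,
    "ENSG1\tTP53\tlung\tpneumocytes\tHigh\tEnhanced",
    "ENSG1\tTP53\tliver\thepatocytes\tN/A\tSupported",
    "ENSG2\tALB\tliver\thepatocytes\tlow\tapproved",
    "ENSG2\tALB\tlung\tpneumocytes\tNot detected\tUncertain",
    "ENSG3\tINS\tpancreas\tislets\tHigh\tSupported"
  ))
  tbl2 <- read_normal_tissue(path2)
  expect_equal(nrow(tbl2), 4)
  expect_equal(parse_report(tbl2)$n_dropped_level, 1)
  # case-insensitive vocabulary normalization
  expect_true("Low" %in% tbl2$level)
  expect_true("Approved" %in% tbl2$reliability)
})

test_that("parse is loss-counting: retained plus dropped equals total", {
  path <- write_tsv_fixture(c(
    normal_header,
    "E1\tA\tlung\tpneumocytes\tHigh\tEnhanced",
    "E2\tB\tlung\tpneumocytes\tweird\tEnhanced",
    "E3\tC\tlung\tpneumocytes\tLow\tnonsense",
    "E4\t\tlung\tpneumocytes\tLow\tEnhanced",
    "E5\tD\tlung\tpneumocytes\tMedium\tSupported"
  ))
  tbl <- read_normal_tissue(path)
  rep <- parse_report(tbl)
  dropped <- rep$n_dropped_level + rep$n_dropped_reliability + rep$n_dropped_gene
  expect_equal(rep$n_retained + dropped, rep$n_total)
  expect_equal(nrow(tbl), rep$n_retained)
  expect_equal(rep$n_dropped_level, 1)
  expect_equal(rep$n_dropped_reliability, 1)
  expect_equal(rep$n_dropped_gene, 1)
})

test_that("schema and empty-input problems are distinct, named errors", {
  no_rel <- write_tsv_fixture(c(
    "Gene\tGene name\tTissue\tCell type\tLevel",
    "E1\tA\tlung\tpneumocytes\tHigh"
  ))
  expect_error(read_normal_tissue(no_rel), "Reliability",
               class = "cellstainr_error_schema")
  empty <- write_tsv_fixture(character(0))
  expect_error(read_normal_tissue(empty), class = "cellstainr_error_empty_input")
  header_only <- write_tsv_fixture(normal_header)
  expect_error(read_normal_tissue(header_only),
               class = "cellstainr_error_empty_input")
  expect_error(read_normal_tissue(file.path(tempdir(), "nope.tsv")),
               class = "cellstainr_error_io")
})

cancer_header <- "Gene\tGene name\tCancer\tHigh\tMedium\tLow\tNot detected"

test_that("cancer table parsing handles counts, blanks and bad cells", {
  path <- write_tsv_fixture(c(
    cancer_header,
    "E1\tA\tbreast cancer\t3\t2\t1\t4",
    "E2\tB\tbreast cancer\t\t\t\t",
    "E3\tC\tlung cancer\t0\t0\t0\t5"
  ))
  tbl <- read_cancer(path)
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$n_high[tbl$gene_name == "A"], 3L)
  expect_equal(tbl$n_not_detected[tbl$gene_name == "A"], 4L)
  expect_equal(parse_report(tbl)$n_dropped_blank, 1)

  bad <- write_tsv_fixture(c(
    cancer_header,
    "E1\tA\tbreast cancer\t3\t2\t1\t4",
    "E2\tB\tbreast cancer\t2.5\t0\t0\t1"
  ))
  expect_error(read_cancer(bad), "line 3", class = "cellstainr_error_parse")
})

test_that("query parsing splits on any separator, folds case, de-duplicates", {
  q <- parse_query("PRSS1, PNLIP CELA3A\nPRL")
  expect_equal(q$tokens, c("PRSS1", "PNLIP", "CELA3A", "PRL"))
  expect_equal(q$n_unique, 4)

  expect_equal(parse_query("tp53,TP53 , tp53")$tokens, "TP53")
  expect_equal(parse_query(c("a", "B", "a"))$tokens, c("A", "B"))

  expect_error(parse_query(",,  \n"), class = "cellstainr_error_empty_query")
  expect_error(parse_query(NULL), class = "cellstainr_error_empty_query")

  # idempotence: re-parsing the joined tokens yields the same tokens
  for (raw in c("x y z", "B,a\nb c,A", "one")) {
    tokens <- parse_query(raw)$tokens
    expect_equal(parse_query(paste(tokens, collapse = ","))$tokens, tokens)
  }
})

test_that("result CSV round-trips with two-decimal scores", {
  res <- score_query(worked_example_fixture(), "PRSS1 PNLIP CELA3A PRL")
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(res))
  expect_equal(back$cell_type_key, res$cell_type_key)
  expect_equal(back$staining_score, round(res$staining_score, 2))
  expect_equal(back$confidence_score, round(res$confidence_score, 2))
  # the formatting rule itself: always two decimals in the file
  raw <- readLines(path)
  expect_match(raw[2], "75\\.00")
  expect_match(raw[4], "12\\.50")

  expect_error(write_results(res[0, ], path),
               class = "cellstainr_error_empty_input")
})
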