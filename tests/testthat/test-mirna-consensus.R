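record <- function(tool, mirna, ...) {
  tibble::tibble(tool = tool, mirna = normalize_mirna_id(mirna), gene = "ATM", ...)
}

test_that("per-tool thresholds honour strict and non-strict boundaries", {
  recs <- dplyr::bind_rows(
    record("mirdb", "miR-a", prediction_score = 80),     # strict >80: out
    record("mirdb", "miR-b", prediction_score = 80.01),  # in
    record("diana", "miR-c", mitg_score = 0.7),          # >=0.7: in
    record("diana", "miR-d", mitg_score = 0.699),        # out
    record("rna22", "miR-e", p_value = 0.05),            # strict <0.05: out
    record("rna22", "miR-f", p_value = 0.049),           # in
    # TargetScan disjunction: weak context+ rescued by PCT
    record("targetscan", "miR-g", context_plus = -0.05, pct = 0.6),   # in
    record("targetscan", "miR-h", context_plus = -0.1, pct = 0.1),    # in (<= -0.1)
    record("targetscan", "miR-i", context_plus = -0.05, pct = 0.49)   # out
  )
  pass <- apply_tool_filters(recs)
  expect_identical(pass$mirdb, "hsa-miR-b")
  expect_identical(pass$diana, "hsa-miR-c")
  expect_identical(pass$rna22, "hsa-miR-f")
  expect_setequal(pass$targetscan, c("hsa-miR-g", "hsa-miR-h"))
})

test_that("each miRNA is judged on its best record per tool", {
  recs <- dplyr::bind_rows(
    record("mirdb", "miR-multi", prediction_score = 60),
    record("mirdb", "miR-multi", prediction_score = 92),  # best wins
    record("rna22", "miR-multi", p_value = 0.3),
    record("rna22", "miR-multi", p_value = 0.01)          # best (min) wins
  )
  pass <- apply_tool_filters(recs)
  expect_identical(pass$mirdb, "hsa-miR-multi")
  expect_identical(pass$rna22, "hsa-miR-multi")
})

test_that("consensus keeps >= min_tools support and reports disjoint venn cells", {
  sets <- list(
    diana = c("x", "y"), mirdb = "x", targetscan = "x", rna22 = "y"
  )
  res <- consensus(sets, min_tools = 3)
  expect_identical(res$kept, "x")
  venn <- res$venn
  expect_equal(venn$n[venn$tools == "diana+mirdb+targetscan"], 1L)
  expect_equal(venn$n[venn$tools == "diana+rna22"], 1L)
  expect_equal(sum(venn$n), 2L)  # cells sum to the union

  # identical four sets: all mass in the 4-tool cell
  same <- list(diana = c("a", "b"), mirdb = c("a", "b"),
               targetscan = c("a", "b"), rna22 = c("a", "b"))
  res4 <- consensus(same)
  expect_setequal(res4$kept, c("a", "b"))
  expect_equal(res4$venn$n[res4$venn$n_tools == 4], 2L)
  expect_equal(sum(res4$venn$n), 2L)

  # support in exactly 2 tools is dropped at min_tools = 3, kept at 2
  two <- list(diana = "z", mirdb = "z", targetscan = character(0),
              rna22 = character(0))
  expect_length(consensus(two, min_tools = 3)$kept, 0L)
  expect_identical(consensus(two, min_tools = 2)$kept, "z")

  expect_error(consensus(list(diana = "x")), "four")
})

test_that("tidy and glance summarise consensus results", {
  sets <- list(diana = c("a", "b"), mirdb = c("a",  "c"),
               targetscan = "a", rna22 = c("a", "b"))
  res <- consensus(sets)
  td <- tidy(res)
  expect_identical(td$mirna[td$kept], "a")
  expect_equal(td$n_tools[td$mirna == "b"], 2L)
  expect_equal(glance(res)$n_union, 3L)
})

test_that("relaxing a threshold never shrinks the kept set", {
  spec <- synthetic_spec(seed = 13L, n_mirnas = 60L, n_planted = 12L,
                         noise_rate = 0.5)
  gen <- gen_prediction_tables(spec)
  dir <- withr::local_tempdir()
  recs <- dplyr::bind_rows(purrr::imap(gen$tables, function(tbl, tool) {
    path <- file.path(dir, paste0(tool, ".csv"))
    readr::write_csv(tbl, path)
    read_prediction_table(path, tool)
  }))
  base_kept <- consensus(apply_tool_filters(recs))$kept
  relaxed <- consensus(apply_tool_filters(
    recs, thresholds = list(mirdb_score = 60)
  ))$kept
  expect_true(all(base_kept %in% relaxed))
  # raising min_tools never grows the kept set
  stricter <- consensus(apply_tool_filters(recs), min_tools = 4)$kept
  expect_true(all(stricter %in% base_kept))
})

test_that("export dialects round-trip through the packaged column mapping", {
  spec <- synthetic_spec(seed = 3L, n_mirnas = 30L, n_planted = 6L,
                         noise_rate = 0.3)
  gen <- gen_prediction_tables(spec)
  dir <- withr::local_tempdir()
  for (tool in consensus_tools()) {
    readr::write_csv(gen$tables[[tool]], file.path(dir, paste0(tool, ".csv")))
  }
  recs <- dplyr::bind_rows(lapply(consensus_tools(), function(tool) {
    read_prediction_table(file.path(dir, paste0(tool, ".csv")), tool)
  }))
  expect_true(all(c("tool", "mirna", "gene") %in% names(recs)))
  expect_true(all(startsWith(recs$mirna, "hsa-")))
  # planted miRNAs pass in at least three tools
  pass <- apply_tool_filters(recs)
  planted <- gen$truth$mirna[gen$truth$planted]
  support <- vapply(planted, function(m) {
    sum(vapply(pass, function(s) m %in% s, logical(1)))
  }, integer(1))
  expect_true(all(support >= 3))
})

test_that("miRNA id normalization is case- and prefix-insensitive", {
  expect_identical(normalize_mirna_id(c("MiR-181b-5p", "hsa-mir-181b-5p")),
                   rep("hsa-miR-181b-5p", 2))
  expect_identical(normalize_mirna_id("hsa-let-7a-5p"), "hsa-let-7a-5p")
})
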