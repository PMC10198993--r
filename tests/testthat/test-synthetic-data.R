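test_that("synthetic specs validate their parameters", {
  expect_error(synthetic_spec(n_planted = 20, n_mirnas = 10), "n_planted")
  expect_error(synthetic_spec(noise_rate = 1.5), "noise_rate")
  expect_error(synthetic_spec(accessible_windows = list(c(0, 10))), "within")
  expect_error(synthetic_spec(profile_length = 50,
                              accessible_windows = list(c(10, 60))), "within")
  expect_error(synthetic_spec(accessible_windows = list(c(10, 20), c(15, 30))),
               "disjoint")
})

test_that("identical specs generate identical outputs", {
  spec <- synthetic_spec(seed = 17L, n_nodes = 40L, n_mirnas = 30L,
                         n_planted = 5L, noise_rate = 0.4,
                         profile_length = 200L,
                         accessible_windows = list(c(20L, 60L)))
  expect_identical(gen_ppi_network(spec), gen_ppi_network(spec))
  expect_identical(gen_prediction_tables(spec), gen_prediction_tables(spec))
  expect_identical(gen_accessibility_profile(spec),
                   gen_accessibility_profile(spec))

  # byte-identical files from a written bundle
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_synthetic_bundle(spec, d1)
  p2 <- write_synthetic_bundle(spec, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("preferential-attachment networks are heavy-tailed, random graphs are not", {
  # BA with m = n - 1 collapses to the complete graph K5
  k5 <- gen_ppi_network(synthetic_spec(seed = 1L, n_nodes = 5L,
                                       attachment_m = 4L), "barabasi_albert")
  expect_equal(nrow(k5$edges), 10L)
  expect_true(all(node_degrees(k5)$degree == 4L))

  ba <- gen_ppi_network(synthetic_spec(seed = 7L, n_nodes = 200L,
                                       attachment_m = 2L), "barabasi_albert")
  fit <- fit_power_law(ba)
  expect_gte(fit$gamma, 1.5)
  expect_lte(fit$gamma, 3.5)
  # BA graphs are connected and scores survive the default read filter
  expect_true(igraph::is_connected(mirfish:::as_igraph(ba)))
  expect_true(all(ba$edges$combined_score > 0.4 &
                    ba$edges$combined_score <= 1))

  # ER degree law is binomial: the log-log line fits poorly on average
  r2 <- vapply(1:20, function(s) {
    er <- gen_ppi_network(synthetic_spec(seed = s, n_nodes = 50L, er_p = 0.5),
                          "erdos_renyi")
    fit_power_law(er)$r_squared
  }, numeric(1))
  expect_lt(median(r2), 0.9)

  expect_error(
    gen_ppi_network(synthetic_spec(seed = 1L, n_nodes = 3L, attachment_m = 4L),
                    "barabasi_albert"),
    "attachment_m"
  )
})

test_that("planted prediction tables are recovered by the consensus", {
  # noiseless: consensus equals the planted set exactly
  clean <- synthetic_spec(seed = 23L, n_mirnas = 40L, n_planted = 8L,
                          noise_rate = 0)
  gen <- gen_prediction_tables(clean)
  recs <- dplyr::bind_rows(purrr::imap(gen$tables, function(tbl, tool) {
    dir <- withr::local_tempdir(.local_envir = parent.frame(2))
    path <- file.path(dir, paste0(tool, ".csv"))
    readr::write_csv(tbl, path)
    read_prediction_table(path, tool)
  }))
  kept <- consensus(apply_tool_filters(recs))$kept
  expect_setequal(kept, gen$truth$mirna[gen$truth$planted])

  # no plants: empty consensus
  none <- gen_prediction_tables(synthetic_spec(seed = 2L, n_mirnas = 20L,
                                               n_planted = 0L, noise_rate = 0.5))
  recs0 <- dplyr::bind_rows(purrr::imap(none$tables, function(tbl, tool) {
    tbl2 <- tbl
    names(tbl2) <- names(tbl)
    dir <- withr::local_tempdir(.local_envir = parent.frame(2))
    path <- file.path(dir, paste0(tool, ".csv"))
    readr::write_csv(tbl2, path)
    read_prediction_table(path, tool)
  }))
  expect_length(consensus(apply_tool_filters(recs0))$kept, 0L)

  # noisy tables still contain every planted miRNA in the consensus
  noisy <- synthetic_spec(seed = 3L, n_mirnas = 100L, n_planted = 10L,
                          noise_rate = 0.2)
  gen2 <- gen_prediction_tables(noisy)
  recs2 <- dplyr::bind_rows(purrr::imap(gen2$tables, function(tbl, tool) {
    dir <- withr::local_tempdir(.local_envir = parent.frame(2))
    path <- file.path(dir, paste0(tool, ".csv"))
    readr::write_csv(tbl, path)
    read_prediction_table(path, tool)
  }))
  kept2 <- consensus(apply_tool_filters(recs2))$kept
  planted2 <- gen2$truth$mirna[gen2$truth$planted]
  expect_true(all(planted2 %in% kept2))
})

test_that("generated profiles place probability mass exactly in the windows", {
  spec <- synthetic_spec(seed = 29L, profile_length = 9L,
                         accessible_windows = list(c(1L, 5L), c(7L, 9L)))
  profile <- gen_accessibility_profile(spec)
  regions <- call_accessible_regions(profile)
  expect_equal(regions$start, c(1L, 7L))
  expect_equal(regions$end, c(5L, 9L))
  expect_lte(profile$probability[6], 0.5)

  lone <- gen_accessibility_profile(
    synthetic_spec(seed = 31L, profile_length = 40L,
                   accessible_windows = list(c(10L, 20L)))
  )
  r <- call_accessible_regions(lone)
  expect_equal(as.integer(c(r$start, r$end)), c(10L, 20L))

  closed <- gen_accessibility_profile(
    synthetic_spec(seed = 37L, profile_length = 30L,
                   accessible_windows = list())
  )
  expect_equal(nrow(call_accessible_regions(closed)), 0L)
})

test_that("packaged fixtures carry the printed tables unchanged", {
  table1 <- load_fixture("table1")
  expect_equal(nrow(table1), 25L)
  expect_true(all(c("ATM", "APEX1", "CYP1B1", "VDR") %in% table1$gene_symbol))

  table2 <- load_fixture("table2")
  expect_equal(nrow(table2), 14L)
  expect_equal(sum(table2$evidence), 5L)
  atm_row <- dplyr::filter(table2, mirna == "hsa-miR-181b-5p")
  expect_equal(atm_row$logit_prob, 0.863551)
  expect_equal(atm_row$dg_hybrid, -20.5)
  expect_equal(c(atm_row$site_start, atm_row$site_end), c(3505, 3531))

  expect_length(load_fixture("hub_top10"), 10L)
  expect_length(load_fixture("apoptosis_set"), 14L)
  expect_error(load_fixture("nonsense"))

  # transcription integrity: frozen checksums of the packaged tables
  sums <- tools::md5sum(vapply(
    c("table1_targets.csv", "table2_candidates.csv", "hub_top10.txt",
      "apoptosis_annotation.tsv"),
    function(f) system.file("extdata", f, package = "mirfish"),
    character(1)
  ))
  expect_identical(unname(sums), c(
    "4dcee88862bdb7704a236bef39dddc86", "738267a27c9591fbbb2ac9fa489d4770",
    "d4785d1a61fb4b42b76958336ca34d40", "a4698b4fef9418f45fb01e65c6e99592"
  ))
})
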