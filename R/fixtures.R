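#' Packaged reference fixtures
#'
#' The package ships the printed endpoints of the prioritization as plain
#' text fixtures, so the full pipeline can run and be tested offline:
#'
#' * `"table1"` — the 25 predicted protein targets of the query compound
#'   (ChEMBL id, target name, gene symbol), transcribed verbatim.
#' * `"table2"` — the 14 candidate miRNA binding sites on the ATM 3'UTR
#'   (site position 1-based inclusive, LogitProb, dG hybrid in kcal/mol)
#'   with the literature-evidence flag for the five experimentally
#'   supported miRNAs.
#' * `"hub_top10"` — the printed top-10 MCC hub proteins, in rank order.
#' * `"apoptosis_set"` — the 14 network proteins annotated to the
#'   apoptotic process.
#' * `"interactome"` — a synthetic STRING-format interactome constructed so
#'   that seed expansion reproduces the printed 35-protein / 110-interaction
#'   analysis network (the paper's edge list is not deposited; this
#'   stand-in is labelled synthetic).
#' * `"candidates"` — synthetic 22-row candidate-site table: the 14 real
#'   sites plus 8 synthetic decoys placed outside accessible regions.
#' * `"predictions"` — paths to four synthetic predictor exports whose
#'   consensus yields exactly those 22 miRNAs.
#' * `"annotation"` — path to the packaged apoptosis annotation TSV.
#' * `"profile"` — synthetic accessibility profile whose accessible windows
#'   are the merged Table-2 site ranges.
#'
#' @param name One of the fixture names above.
#' @return A tibble, character vector, `interaction_graph`,
#'   `accessibility_profile`, or named path vector, depending on `name`.
#' @export
#' @examples
#' nrow(load_fixture("table1"))
#' load_fixture("hub_top10")
load_fixture <- function(name = c("table1", "table2", "hub_top10",
                                  "apoptosis_set", "interactome",
                                  "candidates", "predictions", "annotation",
                                  "profile")) {
  name <- match.arg(name)
  switch(name,
    table1 = readr::read_csv(extdata_path("table1_targets.csv"),
                             show_col_types = FALSE, progress = FALSE),
    table2 = read_candidate_sites(extdata_path("table2_candidates.csv")),
    hub_top10 = readr::read_lines(extdata_path("hub_top10.txt"),
                                  progress = FALSE),
    apoptosis_set = read_annotation(extdata_path("apoptosis_annotation.tsv")),
    interactome = read_edge_list(
      extdata_path("interactome_synthetic.tsv"),
      seeds = readr::read_csv(extdata_path("table1_targets.csv"),
                              show_col_types = FALSE,
                              progress = FALSE)$gene_symbol
    ),
    candidates = read_candidate_sites(
      extdata_path("candidate_sites_synthetic.csv")
    ),
    predictions = c(
      diana = extdata_path("predictions_diana_synthetic.csv"),
      mirdb = extdata_path("predictions_mirdb_synthetic.csv"),
      targetscan = extdata_path("predictions_targetscan_synthetic.csv"),
      rna22 = extdata_path("predictions_rna22_synthetic.csv")
    ),
    annotation = extdata_path("apoptosis_annotation.tsv"),
    profile = fixture_profile()
  )
}

# Synthetic accessibility profile for the ATM 3'UTR: the folding server's
# probability histogram is not deposited, so the profile is generated with
# accessible windows equal to the merged Table-2 site ranges (all 14 printed
# candidates hybridize to accessible regions). Fixed seed: the fixture is
# the same object in every session.
fixture_profile <- function(utr_length = 3561L) {
  sites <- read_candidate_sites(extdata_path("table2_candidates.csv"))
  merged <- merge_windows(sites$site_start, sites$site_end)
  spec <- synthetic_spec(
    seed = 42L, profile_length = utr_length,
    accessible_windows = merged
  )
  gen_accessibility_profile(spec)
}

# merge possibly-overlapping 1-based inclusive windows into disjoint ones
merge_windows <- function(start, end) {
  ord <- order(start, end)
  start <- start[ord]
  end <- end[ord]
  out_s <- start[1L]
  out_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[[i]] <= out_e[[length(out_e)]] + 1L) {
      out_e[[length(out_e)]] <- max(out_e[[length(out_e)]], end[[i]])
    } else {
      out_s <- c(out_s, start[[i]])
      out_e <- c(out_e, end[[i]])
    }
  }
  tibble(start = as.integer(out_s), end = as.integer(out_e))
}
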