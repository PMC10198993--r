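#' Specification for synthetic pipeline inputs
#'
#' Bundles every knob of the synthetic-data generators with a seed, so a
#' fixed spec reproduces identical outputs byte for byte.
#'
#' @param seed Integer RNG seed.
#' @param n_nodes Number of network nodes.
#' @param attachment_m Preferential-attachment edges per new node
#'   (Barabasi-Albert model).
#' @param er_p Edge probability for the Erdos-Renyi model.
#' @param n_mirnas Size of the synthetic miRNA pool.
#' @param n_planted Number of planted true targets (`<= n_mirnas`).
#' @param noise_rate Probability that a non-planted miRNA emits decoy rows.
#' @param profile_length Length of the synthetic 3'UTR (nt).
#' @param accessible_windows List/tibble of disjoint `(start, end)` windows
#'   (1-based inclusive) planted as accessible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, n_nodes = 100L, attachment_m = 2L,
                           er_p = 0.1, n_mirnas = 100L, n_planted = 10L,
                           noise_rate = 0.2, profile_length = 3000L,
                           accessible_windows = list(c(100L, 200L))) {
  seed <- assert_count(seed, "seed")
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 2L)
  attachment_m <- assert_count(attachment_m, "attachment_m", min = 1L)
  assert_probability(er_p, "er_p")
  n_mirnas <- assert_count(n_mirnas, "n_mirnas")
  n_planted <- assert_count(n_planted, "n_planted")
  assert_probability(noise_rate, "noise_rate")
  profile_length <- assert_count(profile_length, "profile_length", min = 1L)
  if (n_planted > n_mirnas) abort("`n_planted` must be <= `n_mirnas`.")

  windows <- normalize_windows(accessible_windows)
  if (nrow(windows)) {
    if (any(windows$start < 1L) || any(windows$end > profile_length)) {
      abort("accessible windows must lie within [1, profile_length].")
    }
    if (any(windows$start > windows$end)) {
      abort("window start must be <= end.")
    }
    if (nrow(windows) > 1L &&
        any(windows$start[-1L] <= windows$end[-nrow(windows)])) {
      abort("accessible windows must be disjoint.")
    }
  }
  structure(
    list(seed = seed, n_nodes = n_nodes, attachment_m = attachment_m,
         er_p = er_p, n_mirnas = n_mirnas, n_planted = n_planted,
         noise_rate = noise_rate, profile_length = profile_length,
         accessible_windows = windows),
    class = "synthetic_spec"
  )
}

normalize_windows <- function(w) {
  if (is.data.frame(w)) {
    out <- tibble(start = as.integer(w$start), end = as.integer(w$end))
  } else if (is.list(w)) {
    out <- tibble(
      start = vapply(w, function(x) as.integer(x[[1L]]), integer(1)),
      end = vapply(w, function(x) as.integer(x[[2L]]), integer(1))
    )
  } else if (is.null(w) || !length(w)) {
    out <- tibble(start = integer(0), end = integer(0))
  } else {
    abort("`accessible_windows` must be a list of (start, end) or a data frame.")
  }
  arrange(out, .data$start)
}

#' Generate a synthetic interactome
#'
#' Positive and negative controls for the scale-free network selection:
#' the Barabasi-Albert preferential-attachment model produces connected,
#' heavy-tailed (approximately power-law) networks, while the Erdos-Renyi
#' model produces binomial degree distributions that a power-law fit should
#' reject. Edge confidence scores are drawn uniformly in `(0.4, 1]` — above
#' the default STRING-style confidence floor — so generated networks pass
#' the default read filter unchanged.
#'
#' @param spec A [synthetic_spec()].
#' @param model `"barabasi_albert"` or `"erdos_renyi"`.
#' @return An [interaction_graph()] with nodes `P001`, `P002`, ...
#' @export
gen_ppi_network <- function(spec, model = c("barabasi_albert", "erdos_renyi")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  model <- match.arg(model)
  if (model == "barabasi_albert" && spec$n_nodes < spec$attachment_m + 1L) {
    abort("need n_nodes >= attachment_m + 1 for the Barabasi-Albert model.")
  }
  with_seed(spec$seed, {
    g <- if (model == "barabasi_albert") {
      igraph::sample_pa(spec$n_nodes, m = spec$attachment_m, directed = FALSE,
                        algorithm = "psumtree")
    } else {
      igraph::sample_gnp(spec$n_nodes, p = spec$er_p, directed = FALSE)
    }
    g <- igraph::simplify(g)
    ends <- igraph::as_edgelist(g, names = FALSE)
    name_of <- sprintf("P%03d", seq_len(spec$n_nodes))
    n_edges <- nrow(ends)
    edges <- tibble(
      protein1 = name_of[ends[, 1L]],
      protein2 = name_of[ends[, 2L]],
      # strictly above the 0.4 confidence floor
      combined_score = pmax(0.4 + 0.6 * runif(n_edges), 0.4 + 1e-9)
    )
    interaction_graph(edges, nodes = name_of)
  })
}

#' Generate four synthetic predictor tables with a planted consensus
#'
#' Emulates DIANA-microT-CDS, miRDB, TargetScanHuman and RNA22 exports for
#' one target gene. Planted miRNAs receive passing scores in at least three
#' (randomly three or all four) tools; every other pool member may, with
#' probability `noise_rate`, emit decoy rows that are guaranteed to fail
#' the consensus — either they appear in at most two tools with passing
#' scores, or their scores miss a threshold by at least 0.01 of that
#' threshold's scale. A noiseless spec therefore yields tables whose
#' consensus equals the planted set exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param gene Target gene symbol written into every row. Default `"GENE1"`.
#' @return List with `tables` (named list of four tibbles in each tool's
#'   export dialect) and `truth` (tibble `mirna`, `planted`).
#' @export
gen_prediction_tables <- function(spec, gene = "GENE1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 1L, {
    pool <- sprintf("hsa-mir-%04d-5p", seq_len(spec$n_mirnas))
    planted <- head(pool, spec$n_planted)
    others <- setdiff(pool, planted)

    site_for <- function(n) {
      start <- sample.int(max(spec$profile_length - 30L, 1L), n, replace = TRUE)
      tibble(start = start, end = start + 21L)
    }
    passing_score <- function(tool, n) {
      switch(tool,
        diana = runif(n, 0.71, 1),          # >= 0.7 with margin
        mirdb = runif(n, 81, 100),          # > 80 with margin
        targetscan_ctx = runif(n, -0.6, -0.11),
        targetscan_pct = runif(n, 0.51, 0.95),
        rna22 = runif(n, 1e-4, 0.04)        # < 0.05 with margin
      )
    }
    failing_score <- function(tool, n) {
      switch(tool,
        diana = runif(n, 0, 0.69),
        mirdb = runif(n, 40, 79.2),
        targetscan_ctx = runif(n, -0.09, 0.2),
        targetscan_pct = runif(n, 0, 0.49),
        rna22 = runif(n, 0.06, 0.8)
      )
    }

    rows <- list(diana = list(), mirdb = list(), targetscan = list(),
                 rna22 = list())
    emit <- function(tool, mirna, pass) {
      s <- site_for(1L)
      rows[[tool]][[length(rows[[tool]]) + 1L]] <<- switch(tool,
        diana = tibble(mirna = mirna, gene = gene,
                       mitg = passing_or(tool, pass)),
        mirdb = tibble(mirna = mirna, gene = gene,
                       score = passing_or(tool, pass)),
        targetscan = tibble(mirna = mirna, gene = gene,
                            start = s$start, end = s$end,
                            ctx = if (pass) passing_score("targetscan_ctx", 1L)
                                  else failing_score("targetscan_ctx", 1L),
                            pct = if (pass) passing_score("targetscan_pct", 1L)
                                  else failing_score("targetscan_pct", 1L)),
        rna22 = tibble(mirna = mirna, gene = gene,
                       start = s$start, end = s$end,
                       p = passing_or(tool, pass))
      )
    }
    passing_or <- function(tool, pass) {
      if (pass) passing_score(tool, 1L) else failing_score(tool, 1L)
    }

    tools <- consensus_tools()
    for (m in planted) {
      chosen <- sample(tools, sample(3:4, 1L))
      for (tool in chosen) emit(tool, m, pass = TRUE)
    }
    noisy <- others[runif(length(others)) < spec$noise_rate]
    for (m in noisy) {
      if (runif(1) < 0.5) {
        # appears in <= 2 tools even with passing scores
        for (tool in sample(tools, sample(1:2, 1L))) emit(tool, m, pass = TRUE)
      } else {
        # appears widely but fails every threshold by a clear margin
        for (tool in sample(tools, sample(3:4, 1L))) emit(tool, m, pass = FALSE)
      }
    }

    dialect <- function(tool, tbl) {
      if (!length(tbl)) tbl <- list()
      out <- bind_rows(tbl)
      if (!nrow(out)) {
        out <- switch(tool,
          diana = tibble(mirna = character(0), gene = character(0),
                         mitg = numeric(0)),
          mirdb = tibble(mirna = character(0), gene = character(0),
                         score = numeric(0)),
          targetscan = tibble(mirna = character(0), gene = character(0),
                              start = integer(0), end = integer(0),
                              ctx = numeric(0), pct = numeric(0)),
          rna22 = tibble(mirna = character(0), gene = character(0),
                         start = integer(0), end = integer(0), p = numeric(0))
        )
      }
      # rename to each tool's export dialect (see tool_columns.yml)
      names(out) <- switch(tool,
        diana = c("mirna", "gene_name", "mitg_score")[seq_along(out)],
        mirdb = c("mirna_name", "gene_symbol", "target_score")[seq_along(out)],
        targetscan = c("mirna", "gene_symbol", "utr_start", "utr_end",
                       "context_plus_score", "pct")[seq_along(out)],
        rna22 = c("mirna", "gene", "site_start", "site_end",
                  "p_value")[seq_along(out)]
      )
      out
    }
    tables <- setNames(
      lapply(tools, function(t) dialect(t, rows[[t]])), tools
    )
    list(
      tables = tables,
      truth = tibble(mirna = normalize_mirna_id(pool),
                     planted = pool %in% planted)
    )
  })
}

#' Generate an accessibility profile with planted accessible windows
#'
#' Positions inside the spec's windows receive probabilities drawn in
#' `(0.55, 0.95)`; positions outside in `(0.05, 0.45)`. The margins around
#' the 0.5 calling threshold make region recovery exact by construction.
#'
#' @param spec A [synthetic_spec()].
#' @return An [accessibility_profile()].
#' @export
gen_accessibility_profile <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 2L, {
    p <- runif(spec$profile_length, 0.05, 0.45)
    for (i in seq_len(nrow(spec$accessible_windows))) {
      idx <- seq(spec$accessible_windows$start[[i]],
                 spec$accessible_windows$end[[i]])
      p[idx] <- runif(length(idx), 0.55, 0.95)
    }
    accessibility_profile(p)
  })
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits an interactome TSV, the four predictor tables (CSV), a profile TSV
#' and a synthetic 3'UTR FASTA, plus a `truth.csv` with the planted labels.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_bundle <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    network = file.path(dir, "interactome.tsv"),
    diana = file.path(dir, "predictions_diana.csv"),
    mirdb = file.path(dir, "predictions_mirdb.csv"),
    targetscan = file.path(dir, "predictions_targetscan.csv"),
    rna22 = file.path(dir, "predictions_rna22.csv"),
    profile = file.path(dir, "profile.tsv"),
    utr = file.path(dir, "utr.fasta"),
    truth = file.path(dir, "truth.csv")
  )
  write_edge_list(gen_ppi_network(spec), paths[["network"]])
  preds <- gen_prediction_tables(spec)
  for (tool in consensus_tools()) {
    readr::write_csv(preds$tables[[tool]], paths[[tool]], progress = FALSE)
  }
  profile <- gen_accessibility_profile(spec)
  readr::write_tsv(profile, paths[["profile"]], col_names = FALSE,
                   progress = FALSE)
  utr <- with_seed(spec$seed + 3L, paste(
    sample(c("A", "C", "G", "U"), spec$profile_length, replace = TRUE),
    collapse = ""
  ))
  readr::write_lines(c(">synthetic_3utr", utr), paths[["utr"]])
  readr::write_csv(preds$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
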