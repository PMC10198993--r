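#' Pipeline configuration
#'
#' Collects every input path and threshold of the end-to-end prioritization.
#' Defaults point at the packaged fixtures, so `run_pipeline(pipeline_config())`
#' reproduces the reference analysis offline.
#'
#' @param targets Tibble of seed targets with a `gene_symbol` column, or
#'   `NULL` to fish targets from `library_csv` + `query_structure`.
#' @param library_csv,query_structure Compound library CSV and query
#'   structure string for the target-fishing stage (used when `targets` is
#'   `NULL`).
#' @param interactome Path to a STRING-format edge-list TSV.
#' @param predictions Named character vector of the four predictor export
#'   paths (`diana`, `mirdb`, `targetscan`, `rna22`).
#' @param candidates Path to (or tibble of) the candidate-site table
#'   carrying LogitProb and dG hybrid values.
#' @param annotation Path to the symbol/GO-term TSV.
#' @param annotation_term GO term treated as the apoptosis annotation.
#' @param profile An `accessibility_profile`, path to a profile TSV, or
#'   `NULL` to use the packaged fixture profile.
#' @param sim_min,potency_max_um Target-fishing thresholds.
#' @param score_floor STRING combined-score floor (exclusive).
#' @param first_grid,second_grid Sphere-size grids for network selection.
#' @param top_k Number of MCC hubs to report.
#' @param min_tools Consensus support threshold.
#' @param accessibility_threshold Single-strandedness probability cut-off.
#' @param min_overlap Minimum site/region overlap (nt).
#' @param require_evidence Restrict final ranking to literature-supported
#'   candidates.
#' @param seed RNG seed recorded in the report (the fixture pipeline itself
#'   is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(targets = load_fixture("table1"),
                            library_csv = NULL,
                            query_structure = NULL,
                            interactome = extdata_path("interactome_synthetic.tsv"),
                            predictions = load_fixture("predictions"),
                            candidates = load_fixture("candidates"),
                            annotation = load_fixture("annotation"),
                            annotation_term = "apoptotic process",
                            profile = NULL,
                            sim_min = 0.7, potency_max_um = 150,
                            score_floor = 0.4,
                            first_grid = seq(10L, 100L, by = 10L),
                            second_grid = c(0L, seq(10L, 100L, by = 10L)),
                            top_k = 10L, min_tools = 3L,
                            accessibility_threshold = 0.5,
                            min_overlap = 1L,
                            require_evidence = TRUE,
                            seed = 1L) {
  assert_probability(sim_min, "sim_min")
  assert_scalar_number(potency_max_um, "potency_max_um")
  assert_probability(score_floor, "score_floor")
  assert_probability(accessibility_threshold, "accessibility_threshold")
  cfg <- list(
    targets = targets, library_csv = library_csv,
    query_structure = query_structure, interactome = interactome,
    predictions = predictions, candidates = candidates,
    annotation = annotation, annotation_term = annotation_term,
    profile = profile, sim_min = sim_min, potency_max_um = potency_max_um,
    score_floor = score_floor, first_grid = as.integer(first_grid),
    second_grid = as.integer(second_grid),
    top_k = assert_count(top_k, "top_k", min = 1L),
    min_tools = assert_count(min_tools, "min_tools", min = 1L),
    accessibility_threshold = accessibility_threshold,
    min_overlap = assert_count(min_overlap, "min_overlap", min = 1L),
    require_evidence = isTRUE(require_evidence),
    seed = assert_count(seed, "seed")
  )
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)), parent = e)
  })
}

#' Run the end-to-end prioritization pipeline
#'
#' Executes the stages in order — target fishing (or preloaded seed
#' targets), sphere-expanded network construction with scale-free selection,
#' MCC hub ranking intersected with the apoptosis annotation, four-tool
#' miRNA consensus, accessibility filtering, and rank-sum candidate
#' selection — and returns a structured, machine-readable report of every
#' stage's headline numbers and artifacts.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report`: nested list with `$stages` (per-stage artifacts
#'   and counts), `$funnel` (tibble of stage counts), `$final_candidate`,
#'   and `$provenance` (config hash, seed, package version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()

  # -- stage 1: seed targets -----------------------------------------------
  targets <- run_stage("target_fishing", {
    if (!is.null(config$targets)) {
      tt <- as_tibble(config$targets)
      if (!"gene_symbol" %in% names(tt)) {
        abort("`targets` needs a gene_symbol column.")
      }
      tt
    } else {
      if (is.null(config$library_csv) || is.null(config$query_structure)) {
        abort("need either `targets` or `library_csv` + `query_structure`.")
      }
      fished <- fish_targets(read_compound_library(config$library_csv),
                             config$query_structure,
                             sim_min = config$sim_min,
                             potency_max_um = config$potency_max_um)
      rename(fished, gene_symbol = "target_id")
    }
  })
  seeds <- unique(targets$gene_symbol)
  stages$targets <- list(table = targets, n = length(seeds))

  # -- stage 2: network construction and selection -------------------------
  network_sel <- run_stage("network_selection", {
    interactome <- read_edge_list(config$interactome,
                                  score_floor = config$score_floor,
                                  seeds = seeds)
    cand <- build_candidate_networks(interactome, seeds,
                                     first_grid = config$first_grid,
                                     second_grid = config$second_grid)
    sel <- select_network(cand)
    list(candidates = select(cand, -"graph", -"fit"), selected = sel)
  })
  network <- network_sel$selected$graph[[1L]]
  stages$network <- list(
    fit_table = network_sel$candidates,
    settings = c(first_sphere = network_sel$selected$first_sphere,
                 second_sphere = network_sel$selected$second_sphere),
    graph = network,
    fit = network_sel$selected$fit[[1L]],
    n_nodes = nrow(network$nodes), n_edges = nrow(network$edges)
  )

  # -- stage 3: MCC hubs and apoptosis intersection ------------------------
  hubs <- run_stage("hub_ranking", {
    annotation <- read_annotation(config$annotation,
                                  term = config$annotation_term)
    hub_tbl <- mcc_scores(network)
    hub_tbl$annotated <- hub_tbl$protein %in% annotation
    top <- top_hubs(hub_tbl, config$top_k)
    list(table = hub_tbl, top = top,
         apoptotic_hubs = intersect_annotated(top, annotation))
  })
  stages$hubs <- hubs

  # -- stage 4: miRNA consensus --------------------------------------------
  cons <- run_stage("mirna_consensus", {
    records <- bind_rows(purrr::imap(
      config$predictions[consensus_tools()],
      function(path, tool) read_prediction_table(path, tool)
    ))
    consensus(apply_tool_filters(records), min_tools = config$min_tools)
  })
  stages$consensus <- cons

  # -- stage 5: accessibility filter ---------------------------------------
  access <- run_stage("site_accessibility", {
    profile <- config$profile %||% load_fixture("profile")
    if (is.character(profile)) profile <- read_accessibility_profile(profile)
    regions <- call_accessible_regions(
      profile, threshold = config$accessibility_threshold
    )
    cand <- config$candidates
    if (is.character(cand)) cand <- read_candidate_sites(cand)
    cand <- filter(cand, .data$mirna %in% cons$kept)
    kept <- filter_accessible_sites(cand, regions,
                                    min_overlap = config$min_overlap,
                                    profile_length = nrow(profile))
    list(regions = regions, candidates = kept,
         n_in = nrow(cand), n_accessible = dplyr::n_distinct(kept$mirna))
  })
  stages$accessibility <- access

  # -- stage 6: final ranking ----------------------------------------------
  ranking <- run_stage("candidate_ranking", {
    rank_candidates(access$candidates,
                    require_evidence = config$require_evidence)
  })
  stages$ranking <- ranking
  final <- slice_head(ranking, n = 1L)

  funnel <- tibble(
    stage = c("seed_targets", "network_nodes", "top_hubs", "apoptotic_hubs",
              "consensus_mirnas", "accessible_candidates",
              "evidence_supported", "final_candidate"),
    n = c(length(seeds), nrow(network$nodes), length(hubs$top),
          length(hubs$apoptotic_hubs), length(cons$kept),
          access$n_accessible, sum(access$candidates$evidence), 1L)
  )

  report <- list(
    stages = stages,
    funnel = funnel,
    final_candidate = final,
    provenance = list(
      config_hash = rlang::hash(strip_environments(config)),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("mirfish")),
      thresholds = config[c("sim_min", "potency_max_um", "score_floor",
                            "top_k", "min_tools", "accessibility_threshold",
                            "min_overlap", "require_evidence")]
    )
  )
  class(report) <- "run_report"
  report
}

# config hashing must not depend on incidental closure environments
strip_environments <- function(x) {
  if (is.list(x)) lapply(x, strip_environments) else if (is.function(x)) NULL else x
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  selected network : %d nodes, %d edges (first=%d, second=%d, R^2=%.4f)\n",
              x$stages$network$n_nodes, x$stages$network$n_edges,
              x$stages$network$settings[["first_sphere"]],
              x$stages$network$settings[["second_sphere"]],
              x$stages$network$fit$r_squared))
  cat(sprintf("  top hub          : %s\n", x$stages$hubs$top[[1L]]))
  cat(sprintf("  apoptotic hubs   : %s\n",
              paste(x$stages$hubs$apoptotic_hubs, collapse = ", ")))
  cat(sprintf("  consensus miRNAs : %d\n", length(x$stages$consensus$kept)))
  cat(sprintf("  accessible sites : %d\n", x$stages$accessibility$n_accessible))
  cat(sprintf("  final candidate  : %s (LogitProb %.6f, dG %.1f kcal/mol)\n",
              x$final_candidate$mirna, x$final_candidate$logit_prob,
              x$final_candidate$dg_hybrid))
  invisible(x)
}

#' @export
tidy.run_report <- function(x, ...) {
  x$funnel
}

#' @export
glance.run_report <- function(x, ...) {
  tibble(
    n_seed_targets = x$funnel$n[x$funnel$stage == "seed_targets"],
    n_network_nodes = x$stages$network$n_nodes,
    n_network_edges = x$stages$network$n_edges,
    r_squared = x$stages$network$fit$r_squared,
    gamma = x$stages$network$fit$gamma,
    top_hub = x$stages$hubs$top[[1L]],
    n_consensus = length(x$stages$consensus$kept),
    n_accessible = x$stages$accessibility$n_accessible,
    final_candidate = x$final_candidate$mirna
  )
}

#' Write a run report as JSON plus a plain-text summary
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("writing reports requires the jsonlite package.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "run_report.json")
  txt_path <- file.path(dir, "run_report.txt")
  payload <- list(
    funnel = report$funnel,
    network = list(
      settings = as.list(report$stages$network$settings),
      n_nodes = report$stages$network$n_nodes,
      n_edges = report$stages$network$n_edges,
      gamma = report$stages$network$fit$gamma,
      r_squared = report$stages$network$fit$r_squared,
      fit_table = report$stages$network$fit_table
    ),
    hubs = list(top = report$stages$hubs$top,
                apoptotic = report$stages$hubs$apoptotic_hubs),
    consensus = list(kept = report$stages$consensus$kept,
                     venn = select(report$stages$consensus$venn, -"mirnas")),
    final_candidate = report$final_candidate,
    provenance = report$provenance
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(utils::capture.output(print(report)), txt_path)
  invisible(c(json = json_path, txt = txt_path))
}

#' Relative expression by the 2^-ddCt method
#'
#' Standard RT-qPCR relative quantification: fold change of a target gene in
#' a treated sample versus control, each normalized to a reference gene:
#' `2^-((Ct_target,treated - Ct_ref,treated) - (Ct_target,control -
#' Ct_ref,control))`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Cycle-threshold values (vectorized; must be finite).
#' @return Fold change(s) relative to control.
#' @export
#' @examples
#' relative_expression_ddct(25, 20, 26, 20)  # 2.0
relative_expression_ddct <- function(ct_target_treated, ct_ref_treated,
                                     ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated, ct_target_control,
            ct_ref_control)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    abort("all Ct values must be finite numbers.")
  }
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
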