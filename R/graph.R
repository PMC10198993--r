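#' Protein interaction network container
#'
#' An `interaction_graph` is a light container for an undirected, simple,
#' score-weighted protein network: a `nodes` tibble (`protein`, `role` in
#' `{"seed", "added"}`) and an `edges` tibble (`protein1`, `protein2`,
#' `combined_score` in (0, 1]). Edges are stored with `protein1 < protein2`
#' and deduplicated (max score wins); self-loops are dropped.
#'
#' @param edges Data frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param seeds Character vector of seed proteins (others are `"added"`).
#'   Seeds absent from the edge list are retained as isolated nodes.
#' @param nodes Optional character vector of extra node names to keep even if
#'   they carry no edge.
#'
#' @return An `interaction_graph` object.
#' @export
interaction_graph <- function(edges, seeds = character(), nodes = character()) {
  edges <- as_tibble(edges)
  required <- c("protein1", "protein2", "combined_score")
  if (!all(required %in% names(edges))) {
    abort("`edges` needs columns protein1, protein2, combined_score.")
  }
  edges <- edges |>
    mutate(
      protein1 = as.character(.data$protein1),
      protein2 = as.character(.data$protein2),
      combined_score = as.numeric(.data$combined_score)
    ) |>
    filter(.data$protein1 != .data$protein2)
  # canonical orientation, then dedup keeping the best-supported score
  swap <- edges$protein1 > edges$protein2
  tmp <- edges$protein1[swap]
  edges$protein1[swap] <- edges$protein2[swap]
  edges$protein2[swap] <- tmp
  if (nrow(edges)) {
    edges <- edges |>
      group_by(.data$protein1, .data$protein2) |>
      summarise(combined_score = max(.data$combined_score), .groups = "drop") |>
      arrange(.data$protein1, .data$protein2)
  }

  all_nodes <- sort(unique(c(edges$protein1, edges$protein2,
                             as.character(seeds), as.character(nodes))))
  node_tbl <- tibble(
    protein = all_nodes,
    role = ifelse(all_nodes %in% seeds, "seed", "added")
  )
  structure(list(nodes = node_tbl, edges = edges), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf(
    "<interaction_graph: %d proteins (%d seed), %d interactions>\n",
    nrow(x$nodes), sum(x$nodes$role == "seed"), nrow(x$edges)
  ))
  invisible(x)
}

#' @export
tidy.interaction_graph <- function(x, ...) {
  x$edges
}

#' @export
glance.interaction_graph <- function(x, ...) {
  n <- nrow(x$nodes)
  tibble(
    n_nodes = n,
    n_seeds = sum(x$nodes$role == "seed"),
    n_edges = nrow(x$edges),
    density = if (n > 1) nrow(x$edges) / choose(n, 2) else NA_real_
  )
}

# igraph bridge used by clique enumeration and the synthetic generator
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = graph$nodes$protein)
  )
}

#' Node degrees of an interaction network
#'
#' @param graph An `interaction_graph`.
#' @return A tibble with `protein` and `degree` (isolated nodes have 0).
#' @export
node_degrees <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  counts <- table(c(graph$edges$protein1, graph$edges$protein2))
  tibble(
    protein = graph$nodes$protein,
    degree = as.integer(counts[graph$nodes$protein]) |> tidyr::replace_na(0L)
  )
}

#' Read a STRING-format edge list
#'
#' Parses a three-column TSV (`protein1 TAB protein2 TAB combined_score`,
#' optional header) into an [interaction_graph()]. Scores reported on
#' STRING's 0-1000 integer scale are auto-detected (any value > 1) and
#' normalized by 1000. Edges at or below `score_floor` are dropped — the
#' floor is strict, so a score of exactly 0.4 does not survive the default
#' intermediate-confidence filter. Duplicate undirected edges keep the
#' maximum score.
#'
#' @param path Path to the TSV file.
#' @param score_floor Minimum combined score, exclusive. Default 0.4.
#' @param seeds Optional seed proteins to flag (and keep if isolated).
#'
#' @return An `interaction_graph`.
#' @export
read_edge_list <- function(path, score_floor = 0.4, seeds = character()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  assert_probability(score_floor, "score_floor")
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("edge list is empty.")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))) start <- 2L
  if (start > length(fields)) abort("edge list has a header but no rows.")

  rows <- purrr::map(seq(start, length(fields)), function(i) {
    f <- fields[[i]]
    score <- suppressWarnings(as.numeric(f[3L]))
    if (length(f) < 3L || is.na(score) || !nzchar(f[1L]) || !nzchar(f[2L])) {
      abort(sprintf("malformed edge list row at line %d: '%s'", i, lines[[i]]))
    }
    tibble(protein1 = f[1L], protein2 = f[2L], combined_score = score)
  })
  edges <- bind_rows(rows)
  if (any(edges$combined_score > 1)) {
    edges$combined_score <- edges$combined_score / 1000
  }
  edges <- filter(edges, .data$combined_score > score_floor)
  interaction_graph(edges, seeds = seeds)
}

#' Write an interaction network as a STRING-format edge list
#'
#' @param graph An `interaction_graph`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "interaction_graph"))
  readr::write_tsv(graph$edges, path, progress = FALSE)
  invisible(path)
}

#' Induced subgraph on a node subset
#'
#' @param graph An `interaction_graph`.
#' @param keep Character vector of proteins to retain.
#' @return An `interaction_graph` on `keep`; edge set restricted accordingly.
#' @export
induced_network <- function(graph, keep) {
  stopifnot(inherits(graph, "interaction_graph"))
  keep <- as.character(keep)
  seeds <- graph$nodes$protein[graph$nodes$role == "seed"]
  edges <- filter(graph$edges,
                  .data$protein1 %in% keep & .data$protein2 %in% keep)
  interaction_graph(edges, seeds = intersect(seeds, keep), nodes = keep)
}
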