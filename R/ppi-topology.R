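#' Sphere expansion of a seed set within an interactome
#'
#' Grows an analysis network around a set of seed proteins the way STRING's
#' interactor expansion does: the first sphere adds the `first_sphere`
#' highest-affinity non-seed neighbors of the seeds, the second sphere adds
#' the `second_sphere` highest-affinity new neighbors of the expanded set.
#' Affinity of a candidate is its summed edge score to the current node set;
#' ties break lexicographically by protein symbol so expansion is fully
#' deterministic. The result is the induced subgraph on the selected nodes.
#' Seeds missing from the interactome are kept as isolated (degree-0) nodes
#' and reported via a message.
#'
#' @param interactome An `interaction_graph` (already score-filtered on read).
#' @param seeds Character vector of seed proteins.
#' @param first_sphere Number of first-sphere interactors to add. Default 10.
#' @param second_sphere Number of second-sphere interactors. Default 0.
#'
#' @return An `interaction_graph` whose `nodes$role` flags seeds vs added.
#' @export
expand_network <- function(interactome, seeds, first_sphere = 10L,
                           second_sphere = 0L) {
  stopifnot(inherits(interactome, "interaction_graph"))
  first_sphere <- assert_count(first_sphere, "first_sphere")
  second_sphere <- assert_count(second_sphere, "second_sphere")
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) abort("`seeds` must name at least one protein.")

  missing <- setdiff(seeds, interactome$nodes$protein)
  if (length(missing)) {
    inform(sprintf("%d seed(s) absent from the interactome, kept isolated: %s",
                   length(missing), paste(missing, collapse = ", ")))
  }

  neighbors_of <- function(set, excluded) {
    touching <- filter(interactome$edges,
                       .data$protein1 %in% set | .data$protein2 %in% set)
    setdiff(unique(c(touching$protein1, touching$protein2)), excluded)
  }
  # affinity = summed edge score from candidate to the current node set
  rank_candidates_by_affinity <- function(cand, current, k) {
    if (k == 0L || !length(cand)) return(character())
    touching <- filter(interactome$edges,
                       (.data$protein1 %in% cand & .data$protein2 %in% current) |
                       (.data$protein2 %in% cand & .data$protein1 %in% current))
    if (!nrow(touching)) return(character())
    affinity <- tibble(
      protein = ifelse(touching$protein1 %in% current,
                       touching$protein2, touching$protein1),
      score = touching$combined_score
    ) |>
      group_by(.data$protein) |>
      summarise(score = sum(.data$score), .groups = "drop") |>
      arrange(dplyr::desc(.data$score), .data$protein)
    head(affinity$protein, k)
  }

  first <- rank_candidates_by_affinity(neighbors_of(seeds, seeds), seeds,
                                       first_sphere)
  expanded <- union(seeds, first)
  second <- rank_candidates_by_affinity(neighbors_of(first, expanded),
                                        expanded, second_sphere)
  keep <- union(expanded, second)

  edges <- filter(interactome$edges,
                  .data$protein1 %in% keep & .data$protein2 %in% keep)
  interaction_graph(edges, seeds = seeds, nodes = keep)
}

#' Fit a power law to a network's degree distribution
#'
#' Scale-free networks obey `P(k) ~ k^-gamma`. The fit is an ordinary
#' least-squares regression of `log P(k)` on `log k` over the distinct
#' observed degrees `k >= 1` (isolated nodes are excluded: degree 0 has no
#' logarithm), with `P(k)` the fraction of nodes of degree exactly `k`.
#' No binning is applied and zero-count degrees contribute no point. The
#' returned `gamma` is minus the fitted slope; `r_squared` is the coefficient
#' of determination of the regression and is the scale-freeness score used
#' for network selection.
#'
#' @param graph An `interaction_graph` with at least two distinct positive
#'   degrees.
#' @return A `power_law_fit`: list with `gamma`, `r_squared`, `intercept`,
#'   `n_points`, and the per-degree `points` tibble.
#' @export
fit_power_law <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  deg <- node_degrees(graph)
  deg <- filter(deg, .data$degree >= 1L)
  n_total <- nrow(deg)
  pts <- deg |>
    dplyr::count(.data$degree, name = "n_k") |>
    mutate(p_k = .data$n_k / n_total)
  if (nrow(pts) < 2L) {
    abort("degenerate degree distribution: need >= 2 distinct positive degrees.")
  }
  fit <- lm(log(p_k) ~ log(degree), data = pts)
  # summary.lm warns on exact fits; R^2 = 1 is a legitimate outcome here
  fit_summary <- suppressWarnings(summary(fit))
  structure(
    list(
      gamma = -unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r_squared = fit_summary$r.squared,
      n_points = nrow(pts),
      points = as_tibble(pts)
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit: gamma = %.3f, R^2 = %.4f over %d degree points>\n",
              x$gamma, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  x$points
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(gamma = x$gamma, r_squared = x$r_squared, n_points = x$n_points)
}

#' @describeIn fit_power_law log-log degree distribution with the fitted line.
#' @param object A `power_law_fit`.
#' @param ... Ignored.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = log(.data$degree), y = log(.data$p_k))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = -object$gamma,
                         linetype = "dashed") +
    ggplot2::labs(
      x = "log k", y = "log P(k)",
      title = sprintf("Degree distribution: gamma = %.2f, R² = %.3f",
                      object$gamma, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Build and fit a grid of candidate networks, keep the most scale-free
#'
#' `build_candidate_networks()` expands the seed set under every combination
#' of sphere sizes and fits each network's degree distribution.
#' `select_network()` picks the candidate with the highest R-squared —
#' the network most consistent with a scale-free topology — breaking ties by
#' smaller node count, then by lexicographically smallest settings.
#' Candidates whose degree distribution is degenerate (fewer than two
#' distinct positive degrees) are reported with `NA` fit values and never
#' selected.
#'
#' @param interactome An `interaction_graph`.
#' @param seeds Seed proteins.
#' @param first_grid,second_grid Integer vectors of sphere sizes to try.
#' @return For `build_candidate_networks()`: a tibble with columns
#'   `first_sphere`, `second_sphere`, `n_nodes`, `n_edges`, `gamma`,
#'   `r_squared`, and list-columns `graph`, `fit`.
#' @export
build_candidate_networks <- function(interactome, seeds,
                                     first_grid = seq(10L, 100L, by = 10L),
                                     second_grid = c(0L, seq(10L, 100L, by = 10L))) {
  grid <- tidyr::expand_grid(first_sphere = as.integer(first_grid),
                             second_sphere = as.integer(second_grid))
  rows <- purrr::pmap(grid, function(first_sphere, second_sphere) {
    g <- expand_network(interactome, seeds, first_sphere, second_sphere)
    fit <- tryCatch(fit_power_law(g), error = function(e) NULL)
    tibble(
      first_sphere = first_sphere, second_sphere = second_sphere,
      n_nodes = nrow(g$nodes), n_edges = nrow(g$edges),
      gamma = if (is.null(fit)) NA_real_ else fit$gamma,
      r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
      graph = list(g), fit = list(fit)
    )
  })
  bind_rows(rows)
}

#' @rdname build_candidate_networks
#' @param candidates A tibble as returned by `build_candidate_networks()`.
#' @return For `select_network()`: the selected row (one-row tibble with
#'   `graph` and `fit` list-columns).
#' @export
select_network <- function(candidates) {
  valid <- filter(candidates, !is.na(.data$r_squared))
  if (!nrow(valid)) abort("all candidate networks have degenerate degree distributions.")
  valid |>
    arrange(dplyr::desc(.data$r_squared), .data$n_nodes,
            .data$first_sphere, .data$second_sphere) |>
    slice_head(n = 1L)
}
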