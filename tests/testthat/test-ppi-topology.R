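write_edges <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_edge_list filters, normalizes and deduplicates STRING edges", {
  g <- read_edge_list(write_edges(c("A\tB\t0.5", "B\tC\t0.9", "C\tD\t0.41")))
  expect_equal(nrow(g$edges), 3L)

  # strictly-greater-than floor: 0.4 exactly is dropped
  g <- read_edge_list(write_edges(c("A\tB\t0.4", "B\tC\t0.41")))
  expect_equal(nrow(g$edges), 1L)
  expect_identical(g$edges$protein1, "B")

  # 0-1000 integer scale auto-normalized
  g <- read_edge_list(write_edges(c("A\tB\t700", "B\tC\t950")))
  expect_equal(sort(g$edges$combined_score), c(0.7, 0.95))

  # header tolerated; duplicate undirected edge keeps the max score
  g <- read_edge_list(write_edges(c(
    "protein1\tprotein2\tcombined_score", "A\tB\t0.6", "B\tA\t0.8"
  )))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$combined_score, 0.8)

  expect_error(read_edge_list(write_edges(c("A\tB\t0.5", "A\tnot_a_row"))),
               "line 2")
})

test_that("sphere expansion adds ranked interactors and nothing else", {
  # chain: s1 - x - y ; x is the only neighbor of the seed, y is distance 2
  chain <- graph_from_pairs(list(c("s1", "x"), c("x", "y")))

  seeds_only <- expand_network(chain, "s1", first_sphere = 0, second_sphere = 0)
  expect_identical(seeds_only$nodes$protein, "s1")
  expect_equal(nrow(seeds_only$edges), 0L)

  no_second <- expand_network(chain, "s1", first_sphere = 5, second_sphere = 0)
  expect_setequal(no_second$nodes$protein, c("s1", "x"))

  with_second <- expand_network(chain, "s1", first_sphere = 5, second_sphere = 5)
  expect_setequal(with_second$nodes$protein, c("s1", "x", "y"))

  # neighbor ranking by summed edge score to the seed set
  star <- interaction_graph(tibble::tibble(
    protein1 = c("s1", "s1", "s1"),
    protein2 = c("hi", "mid", "lo"),
    combined_score = c(0.9, 0.7, 0.5)
  ))
  top1 <- expand_network(star, "s1", first_sphere = 1, second_sphere = 0)
  expect_setequal(top1$nodes$protein, c("s1", "hi"))

  # missing seeds survive as isolated flagged nodes
  expect_message(
    g <- expand_network(chain, c("s1", "ghost"), 1, 0),
    "ghost"
  )
  expect_true("ghost" %in% g$nodes$protein)
  expect_equal(node_degrees(g)$degree[g$nodes$protein == "ghost"], 0L)
})

test_that("enlarging the first sphere never removes nodes", {
  spec <- synthetic_spec(seed = 5L, n_nodes = 60L, attachment_m = 2L)
  g <- gen_ppi_network(spec, "barabasi_albert")
  seeds <- g$nodes$protein[1:5]
  prev <- character(0)
  for (k in c(0, 2, 5, 10, 20)) {
    nodes <- expand_network(g, seeds, first_sphere = k, second_sphere = 0)$nodes$protein
    expect_true(all(prev %in% nodes))
    prev <- nodes
  }
})

test_that("power-law fit recovers exact constructed degree laws", {
  # star with 5 leaves: P(1) = 5/6 at k = 1, P(5) = 1/6 at k = 5 -> gamma 1
  star5 <- gadget_graph(star_sizes = 5)
  fit <- fit_power_law(star5)
  expect_equal(fit$gamma, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # counts 16/4/1 at degrees 1/2/4: exact k^-2 law
  g2 <- gadget_graph(star_sizes = 4, cycle_sizes = 4, n_edges = 6)
  fit2 <- fit_power_law(g2)
  expect_equal(fit2$gamma, 2, tolerance = 1e-9)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit2$n_points, 3L)

  # gamma = 1 at degrees 1/2/4 with counts 8/4/2
  g1 <- gadget_graph(star_sizes = c(4, 4), cycle_sizes = 4)
  fit1 <- fit_power_law(g1)
  expect_equal(fit1$gamma, 1, tolerance = 1e-9)
  expect_equal(fit1$r_squared, 1, tolerance = 1e-9)

  # single distinct degree is degenerate
  expect_error(fit_power_law(complete_graph(4)), "degenerate")

  # glance/tidy expose the fit
  expect_named(glance(fit2), c("gamma", "r_squared", "n_points"))
  expect_equal(sum(tidy(fit2)$p_k), 1)
})

test_that("select_network maximizes R^2 with parsimonious tie-breaks", {
  cand <- tibble::tibble(
    first_sphere = c(10L, 20L, 30L), second_sphere = 0L,
    n_nodes = c(35L, 45L, 55L), n_edges = 0L,
    gamma = 2, r_squared = c(0.81, 0.95, 0.60),
    graph = list(NULL), fit = list(NULL)
  )
  expect_equal(select_network(cand)$first_sphere, 20L)

  # tie on R^2: fewer nodes wins; input order is irrelevant
  tie <- tibble::tibble(
    first_sphere = c(40L, 10L), second_sphere = 0L,
    n_nodes = c(60L, 35L), n_edges = 0L,
    gamma = 2, r_squared = 0.9,
    graph = list(NULL), fit = list(NULL)
  )
  expect_equal(select_network(tie)$first_sphere, 10L)
  expect_equal(select_network(tie[2:1, ])$first_sphere, 10L)

  degenerate <- dplyr::mutate(tie, r_squared = NA_real_)
  expect_error(select_network(degenerate), "degenerate")
})

test_that("candidate grid construction reports a full fit table", {
  spec <- synthetic_spec(seed = 9L, n_nodes = 80L, attachment_m = 2L)
  g <- gen_ppi_network(spec, "barabasi_albert")
  seeds <- g$nodes$protein[1:6]
  cand <- build_candidate_networks(g, seeds, first_grid = c(5L, 10L),
                                   second_grid = c(0L, 5L))
  expect_equal(nrow(cand), 4L)
  expect_true(all(c("gamma", "r_squared", "n_nodes") %in% names(cand)))
  sel <- select_network(cand)
  expect_equal(sel$r_squared, max(cand$r_squared, na.rm = TRUE))
})
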