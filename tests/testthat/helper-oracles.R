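# Independent oracles and small graph builders used across test files.

# interaction_graph from a plain edge matrix/list of character pairs
graph_from_pairs <- function(pairs, score = 0.9, nodes = character()) {
  if (!length(pairs)) {
    edges <- tibble::tibble(protein1 = character(0), protein2 = character(0),
                            combined_score = numeric(0))
  } else {
    m <- do.call(rbind, pairs)
    edges <- tibble::tibble(protein1 = m[, 1], protein2 = m[, 2],
                            combined_score = score)
  }
  interaction_graph(edges, nodes = nodes)
}

complete_graph <- function(n, labels = sprintf("v%02d", seq_len(n))) {
  cmb <- utils::combn(labels, 2)
  graph_from_pairs(lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
}

# Erdos-Renyi random graph as interaction_graph, plain base R
random_small_graph <- function(n, p, seed) {
  set.seed(seed)
  labels <- sprintf("v%02d", seq_len(n))
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (runif(1) < p) pairs[[length(pairs) + 1]] <- c(labels[i], labels[j])
    }
  }
  graph_from_pairs(pairs, nodes = labels)
}

adjacency_of <- function(graph) {
  labels <- graph$nodes$protein
  n <- length(labels)
  adj <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges$protein1[i]
    b <- graph$edges$protein2[i]
    adj[a, b] <- 1L
    adj[b, a] <- 1L
  }
  adj
}

# brute-force maximal-clique enumeration over all vertex subsets (n <= ~12)
oracle_maximal_cliques <- function(graph) {
  adj <- adjacency_of(graph)
  labels <- graph$nodes$protein
  n <- length(labels)
  is_complete <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    m <- adj[idx, idx]
    all(m[upper.tri(m)] == 1L)
  }
  cliques <- list()
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!length(idx) || !is_complete(idx)) next
    outside <- setdiff(seq_len(n), idx)
    extendable <- length(outside) &&
      any(colSums(adj[idx, outside, drop = FALSE]) == length(idx))
    if (!extendable) cliques[[length(cliques) + 1]] <- sort(labels[idx])
  }
  sizes <- lengths(cliques)
  keys <- vapply(cliques, paste, character(1), collapse = "\r")
  cliques[order(-sizes, keys)]
}

# MCC by definition, on top of the brute-force clique oracle
oracle_mcc <- function(graph) {
  cliques <- oracle_maximal_cliques(graph)
  scores <- setNames(numeric(nrow(graph$nodes)), graph$nodes$protein)
  for (cl in cliques) {
    scores[cl] <- scores[cl] + factorial(length(cl) - 1)
  }
  scores
}

# exact degree histograms from disjoint gadgets: a k-star contributes one
# degree-k node and k degree-1 leaves, an m-cycle contributes m degree-2
# nodes, a disjoint edge two degree-1 nodes
gadget_graph <- function(star_sizes = integer(), cycle_sizes = integer(),
                         n_edges = 0) {
  pairs <- list()
  idx <- 0
  for (k in star_sizes) {
    idx <- idx + 1
    centre <- sprintf("c%03d", idx)
    for (j in seq_len(k)) {
      pairs[[length(pairs) + 1]] <- c(centre, sprintf("s%03d_%02d", idx, j))
    }
  }
  for (m in cycle_sizes) {
    idx <- idx + 1
    ring <- sprintf("r%03d_%02d", idx, seq_len(m))
    for (j in seq_len(m)) {
      pairs[[length(pairs) + 1]] <- c(ring[j], ring[j %% m + 1])
    }
  }
  for (i in seq_len(n_edges)) {
    pairs[[length(pairs) + 1]] <- c(sprintf("p%03d_a", i), sprintf("p%03d_b", i))
  }
  graph_from_pairs(pairs)
}
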