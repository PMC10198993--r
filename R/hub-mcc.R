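# ---- exact big-integer helpers ------------------------------------------
# MCC sums (|C|-1)! over maximal cliques; factorials overflow doubles past
# 170 and lose exactness past 18!, so scores are accumulated exactly in
# little-endian base-1e4 limb vectors.

big_from_int <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0L)
  limbs <- integer(0)
  while (x > 0) {
    limbs <- c(limbs, as.integer(x %% 10000))
    x <- x %/% 10000
  }
  limbs
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, integer(n - length(a)))
  b <- c(b, integer(n - length(b)))
  out <- integer(n)
  carry <- 0L
  for (i in seq_len(n)) {
    s <- a[[i]] + b[[i]] + carry
    out[[i]] <- s %% 10000L
    carry <- s %/% 10000L
  }
  if (carry > 0L) out <- c(out, carry)
  out
}

big_mul_small <- function(a, m) {
  stopifnot(m >= 0, m < 10000)
  out <- integer(length(a))
  carry <- 0
  for (i in seq_along(a)) {
    s <- a[[i]] * m + carry
    out[[i]] <- as.integer(s %% 10000)
    carry <- s %/% 10000
  }
  while (carry > 0) {
    out <- c(out, as.integer(carry %% 10000))
    carry <- carry %/% 10000
  }
  out
}

big_factorial <- function(n) {
  out <- big_from_int(1)
  if (n < 2) return(out)
  for (m in 2:n) out <- big_mul_small(out, m)
  out
}

# -1 / 0 / 1 comparison
big_cmp <- function(a, b) {
  a <- rev(a[seq_len(max(which(a != 0L), 1L))])
  b <- rev(b[seq_len(max(which(b != 0L), 1L))])
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in seq_along(a)) {
    if (a[[i]] != b[[i]]) return(sign(a[[i]] - b[[i]]))
  }
  0L
}

big_to_string <- function(a) {
  a <- a[seq_len(max(which(a != 0L), 1L))]
  paste0(a[[length(a)]],
         paste(sprintf("%04d", rev(a[-length(a)])), collapse = ""))
}

big_to_double <- function(a) sum(a * 10000^(seq_along(a) - 1))

# ---- clique enumeration ---------------------------------------------------

#' Enumerate the maximal cliques of a network
#'
#' Bron-Kerbosch enumeration with pivoting on the unweighted topology of the
#' network (edge scores are ignored: a clique is a purely topological
#' object). Isolated nodes contribute their singleton as a maximal clique,
#' so every node appears in at least one clique. Output is deterministic:
#' members of each clique are sorted, and cliques are sorted by decreasing
#' size then lexicographically.
#'
#' @param graph An `interaction_graph`.
#' @return A list of character vectors, each a maximal clique.
#' @export
maximal_cliques <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  nodes <- graph$nodes$protein
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges$protein1[[i]]
    b <- graph$edges$protein2[[i]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }

  cliques <- list()
  bk <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      cliques[[length(cliques) + 1L]] <<- sort(r)
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbors in P
    pux <- c(p, x)
    pivot <- pux[[which.max(vapply(pux, function(u) {
      length(intersect(adj[[u]], p))
    }, integer(1)))]]
    for (v in setdiff(p, adj[[pivot]])) {
      bk(c(r, v), intersect(p, adj[[v]]), intersect(x, adj[[v]]))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(character(0), nodes, character(0))

  sizes <- lengths(cliques)
  keys <- vapply(cliques, paste, character(1), collapse = "\r")
  cliques[order(-sizes, keys)]
}

#' Maximal Clique Centrality (MCC) hub scores
#'
#' For each node `v`, `MCC(v)` is the sum over all maximal cliques `C`
#' containing `v` of `(|C| - 1)!` — the hub score popularized by the
#' CytoHubba Cytoscape plugin. An isolated node scores 1 (its singleton is
#' its only maximal clique and `0! = 1`); such nodes are flagged in the
#' output since conventions for edgeless nodes differ between tools.
#' Factorials and sums are computed in exact integer arithmetic; `mcc` is a
#' double approximation for convenience and `mcc_exact` the exact decimal
#' string used for ranking.
#'
#' @param graph An `interaction_graph`.
#' @return A `hub_table`: tibble with `protein`, `mcc`, `mcc_exact`,
#'   `degree`, `isolated`, sorted by decreasing score (ties by higher
#'   degree, then symbol).
#' @export
mcc_scores <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  cliques <- maximal_cliques(graph)
  nodes <- graph$nodes$protein
  scores <- setNames(replicate(length(nodes), big_from_int(0), simplify = FALSE),
                     nodes)
  fact_cache <- list()
  for (cl in cliques) {
    key <- as.character(length(cl) - 1L)
    if (is.null(fact_cache[[key]])) {
      fact_cache[[key]] <- big_factorial(length(cl) - 1L)
    }
    w <- fact_cache[[key]]
    for (v in cl) scores[[v]] <- big_add(scores[[v]], w)
  }

  deg <- node_degrees(graph)
  tbl <- tibble(
    protein = nodes,
    mcc = unname(vapply(scores, big_to_double, numeric(1))),
    mcc_exact = unname(vapply(scores, big_to_string, character(1))),
    degree = deg$degree[match(nodes, deg$protein)],
    isolated = deg$degree[match(nodes, deg$protein)] == 0L
  )
  ord <- order_by_big(scores[tbl$protein], tbl$degree, tbl$protein)
  tbl <- tbl[ord, ]
  class(tbl) <- c("hub_table", class(tbl))
  tbl
}

# decreasing exact-score order, ties by decreasing degree then symbol
order_by_big <- function(bigs, degree, symbol) {
  n <- length(bigs)
  idx <- seq_len(n)
  gt <- function(i, j) {
    cmp <- big_cmp(bigs[[i]], bigs[[j]])
    if (cmp != 0L) return(cmp > 0L)
    if (degree[[i]] != degree[[j]]) return(degree[[i]] > degree[[j]])
    symbol[[i]] < symbol[[j]]
  }
  # insertion sort: n is small and comparisons are non-vectorizable
  for (i in seq_len(n)[-1]) {
    j <- i
    while (j > 1L && gt(idx[[j]], idx[[j - 1L]])) {
      tmp <- idx[[j]]
      idx[[j]] <- idx[[j - 1L]]
      idx[[j - 1L]] <- tmp
      j <- j - 1L
    }
  }
  idx
}

#' Top-k hub proteins
#'
#' @param hub_table A `hub_table` from [mcc_scores()].
#' @param k Number of hubs to return (all nodes if `k` exceeds the node
#'   count). Default 10.
#' @return Character vector of the `k` highest-scoring proteins, in rank
#'   order (ties already resolved by degree then symbol).
#' @export
top_hubs <- function(hub_table, k = 10L) {
  k <- assert_count(k, "k", min = 1L)
  head(hub_table$protein, k)
}

#' Intersect ranked hubs with an annotation set
#'
#' Order-preserving intersection: the result keeps the hub ranking, so the
#' first element is the highest-ranked annotated hub.
#'
#' @param hubs Character vector of hub symbols in rank order.
#' @param annotation Character vector (or set) of annotated symbols, e.g.
#'   apoptosis-process proteins.
#' @return Character vector of annotated hubs in hub-rank order.
#' @export
intersect_annotated <- function(hubs, annotation) {
  hubs[hubs %in% annotation]
}

#' Read a symbol-to-term annotation table
#'
#' Expects a headerless two-column TSV `symbol TAB go_term`; `#` comment
#' lines are skipped.
#'
#' @param path Path to the TSV.
#' @param term Annotation term to select. Default `"apoptotic process"`.
#' @return Character vector of symbols annotated with `term`.
#' @export
read_annotation <- function(path, term = "apoptotic process") {
  tbl <- readr::read_tsv(path, col_names = c("symbol", "go_term"),
                         col_types = "cc", progress = FALSE, comment = "#")
  unique(tbl$symbol[tbl$go_term == term])
}
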