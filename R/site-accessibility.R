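#' Accessibility profile of a 3'UTR
#'
#' A per-nucleotide single-strandedness probability profile, as produced by
#' partition-function folding servers (the probability that each position is
#' unpaired, hence available for miRNA hybridization). Positions are 1-based
#' on the UTR.
#'
#' @param probabilities Numeric vector of probabilities in `[0, 1]`; index =
#'   nucleotide position.
#' @return An `accessibility_profile`: tibble with `position`, `probability`.
#' @export
accessibility_profile <- function(probabilities) {
  probabilities <- as.numeric(probabilities)
  if (!length(probabilities) || anyNA(probabilities) ||
      any(probabilities < 0 | probabilities > 1)) {
    abort("`probabilities` must be a non-empty vector of values in [0, 1].")
  }
  out <- tibble(position = seq_along(probabilities),
                probability = probabilities)
  class(out) <- c("accessibility_profile", class(out))
  out
}

#' Read a two-column accessibility profile TSV
#'
#' Expects `position TAB probability` rows (optional header), positions
#' 1-based and contiguous from 1.
#'
#' @param path Path to the TSV.
#' @return An `accessibility_profile`.
#' @export
read_accessibility_profile <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- suppressWarnings(
    readr::read_tsv(path, col_names = c("position", "probability"),
                    col_types = "dd", progress = FALSE, comment = "#")
  )
  if (anyNA(tbl$position)) tbl <- tbl[-1L, ]  # header row
  tbl <- arrange(tbl, .data$position)
  if (!identical(as.integer(tbl$position), seq_len(nrow(tbl)))) {
    abort("profile positions must run contiguously from 1.")
  }
  accessibility_profile(tbl$probability)
}

#' Call accessible regions from a probability profile
#'
#' An accessible region is a maximal run of consecutive nucleotides whose
#' single-strandedness probability is strictly greater than `threshold`
#' (default 0.5; a position at exactly the threshold is not accessible).
#'
#' @param profile An `accessibility_profile` (or bare numeric vector).
#' @param threshold Probability cut-off, exclusive. Default 0.5.
#' @return A tibble of disjoint, sorted regions: `start`, `end` (1-based
#'   inclusive), `width`. Zero rows when nothing exceeds the threshold.
#' @export
call_accessible_regions <- function(profile, threshold = 0.5) {
  if (is.numeric(profile)) profile <- accessibility_profile(profile)
  assert_probability(threshold, "threshold")
  open <- profile$probability > threshold
  if (!any(open)) {
    return(tibble(start = integer(0), end = integer(0), width = integer(0)))
  }
  runs <- rle(open)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  tibble(start = starts[runs$values], end = ends[runs$values]) |>
    mutate(width = .data$end - .data$start + 1L)
}

#' Does a candidate site overlap an accessible region?
#'
#' @param site_start,site_end 1-based inclusive site coordinates on the UTR.
#' @param regions Region tibble from [call_accessible_regions()] (sorted,
#'   disjoint).
#' @param min_overlap Minimum overlap in nucleotides required to count as
#'   accessible. Default 1.
#' @param profile_length Optional UTR length; when given, sites outside
#'   `[1, profile_length]` raise an error.
#' @return Logical scalar (vectorized over sites).
#' @export
site_accessible <- function(site_start, site_end, regions, min_overlap = 1L,
                            profile_length = NULL) {
  min_overlap <- assert_count(min_overlap, "min_overlap", min = 1L)
  if (any(site_start > site_end)) abort("site_start must be <= site_end.")
  if (!is.null(profile_length) &&
      any(site_start < 1L | site_end > profile_length)) {
    abort("site lies outside the profile bounds.")
  }
  vapply(seq_along(site_start), function(i) {
    overlap <- pmin(site_end[[i]], regions$end) -
      pmax(site_start[[i]], regions$start) + 1L
    any(overlap >= min_overlap)
  }, logical(1))
}

#' Nearest-neighbor stacking parameters for RNA duplexes
#'
#' Returns the packaged stacking free-energy table: the 16 ordered
#' Watson-Crick pair steps with their Turner-model free energies
#' (kcal/mol at 37 degrees C) and the duplex initiation penalty. The step
#' key `"XY>ZW"` denotes consecutive base pairs X:Y then Z:W read 5'->3'
#' along the first strand. Sources are cited in the data file itself.
#'
#' @return List with `stacks` (tibble `step`, `dg`) and `init_penalty`.
#' @export
duplex_params <- function() {
  tbl <- readr::read_csv(extdata_path("nn_stack_energies.csv"),
                         comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  init <- tbl$dg[tbl$step == "init"]
  list(stacks = filter(tbl, .data$step != "init"), init_penalty = init)
}

wc_partner <- c(A = "U", U = "A", G = "C", C = "G")
is_valid_pair <- function(x, y) {
  (wc_partner[[x]] == y) || (x == "G" && y == "U") || (x == "U" && y == "G")
}

#' Simplified nearest-neighbor duplex free energy
#'
#' Computes the hybridization free energy of a miRNA:target duplex as the
#' initiation penalty plus the sum of stacking energies over consecutive
#' paired steps. This is the additive core of the nearest-neighbor model:
#' loops, bulges and dangling ends contribute nothing here, and stacks
#' involving a G:U wobble (accepted as a valid pair) contribute 0 because
#' the packaged table covers the 16 Watson-Crick steps. More negative means
#' a more stable hybrid.
#'
#' @param mirna_seq miRNA sequence, 5'->3', RNA alphabet (`ACGU`; `T`
#'   accepted and treated as `U`).
#' @param site_seq Target-site sequence, 5'->3'.
#' @param pairing Two-column matrix or data frame of index pairs
#'   `(i on miRNA, j on site)`; pairs must be Watson-Crick or G:U and
#'   non-crossing (the duplex is antiparallel: as `i` increases, `j` must
#'   strictly decrease).
#' @param params Parameter set from [duplex_params()].
#' @return Free energy in kcal/mol.
#' @export
duplex_dg <- function(mirna_seq, site_seq, pairing, params = duplex_params()) {
  clean <- function(s) {
    s <- chartr("tu", "TU", toupper(s))
    s <- gsub("T", "U", s, fixed = TRUE)
    if (!grepl("^[ACGU]+$", s)) abort("sequences must be RNA (ACGU).")
    strsplit(s, "")[[1]]
  }
  a <- clean(mirna_seq)
  b <- clean(site_seq)
  pairing <- as.matrix(as.data.frame(pairing))
  if (nrow(pairing) == 0L) return(params$init_penalty)
  if (ncol(pairing) != 2L) abort("`pairing` needs two columns (i, j).")
  pairing <- pairing[order(pairing[, 1L]), , drop = FALSE]
  i <- pairing[, 1L]
  j <- pairing[, 2L]
  if (any(i < 1L | i > length(a)) || any(j < 1L | j > length(b))) {
    abort("pairing indices outside the sequences.")
  }
  if (any(diff(i) <= 0L) || any(diff(j) >= 0L)) {
    abort("pairing must be non-crossing (i increasing, j decreasing).")
  }
  for (k in seq_along(i)) {
    if (!is_valid_pair(a[[i[[k]]]], b[[j[[k]]]])) {
      abort(sprintf("invalid base pair %s:%s at (%d, %d).",
                    a[[i[[k]]]], b[[j[[k]]]], i[[k]], j[[k]]))
    }
  }

  stacks <- setNames(params$stacks$dg, params$stacks$step)
  dg <- params$init_penalty
  for (k in seq_len(length(i) - 1L)) {
    # a stack requires strictly consecutive pairs on both strands
    if (i[[k + 1L]] == i[[k]] + 1L && j[[k + 1L]] == j[[k]] - 1L) {
      key <- sprintf("%s%s>%s%s", a[[i[[k]]]], b[[j[[k]]]],
                     a[[i[[k + 1L]]]], b[[j[[k + 1L]]]])
      dg <- dg + (stacks[[key]] %||% 0)
    }
  }
  dg
}

#' Read a candidate-site table
#'
#' Expects a CSV with columns `mirna, site_start, site_end, logit_prob,
#' dg_hybrid, evidence` — one row per predicted miRNA binding site with its
#' binding likelihood (`logit_prob`, in `[0, 1]`), hybrid free energy
#' (`dg_hybrid`, kcal/mol) and a logical literature-evidence flag.
#'
#' @param path Path to the CSV.
#' @return A tibble of candidate sites.
#' @export
read_candidate_sites <- function(path) {
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  required <- c("mirna", "site_start", "site_end", "logit_prob",
                "dg_hybrid", "evidence")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(paste0("candidate table missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(tbl$site_start > tbl$site_end)) abort("site_start must be <= site_end.")
  if (any(tbl$logit_prob < 0 | tbl$logit_prob > 1)) {
    abort("logit_prob must lie in [0, 1].")
  }
  tbl$mirna <- normalize_mirna_id(tbl$mirna)
  tbl$evidence <- as.logical(tbl$evidence)
  as_tibble(tbl[required])
}

#' Filter candidate sites by accessibility
#'
#' @param candidates Candidate-site tibble (see [read_candidate_sites()]).
#' @param regions Accessible regions from [call_accessible_regions()].
#' @param min_overlap Minimum overlap (nt) with an accessible region.
#' @param profile_length Optional UTR length for bounds checking.
#' @return The accessible subset of `candidates`, with an `accessible`
#'   column attached.
#' @export
filter_accessible_sites <- function(candidates, regions, min_overlap = 1L,
                                    profile_length = NULL) {
  candidates <- as_tibble(candidates)
  candidates$accessible <- site_accessible(
    candidates$site_start, candidates$site_end, regions,
    min_overlap = min_overlap, profile_length = profile_length
  )
  filter(candidates, .data$accessible)
}

#' Rank candidate miRNAs by binding likelihood and hybrid stability
#'
#' The selection criterion favours the candidate with the highest binding
#' likelihood (`logit_prob`) *and* the most stable hybrid (lowest
#' `dg_hybrid`). The two orderings can disagree in general, so candidates
#' are aggregated by rank-sum: `rank(-logit_prob) + rank(dg_hybrid)`
#' (competition ranking), smaller is better. A candidate that dominates on
#' both criteria always wins. Rank-sum ties break by higher `logit_prob`,
#' then by miRNA id.
#'
#' @param candidates Candidate-site tibble.
#' @param require_evidence Keep only literature-supported candidates
#'   (`evidence == TRUE`) before ranking. Default `FALSE`.
#' @return The tibble sorted best-first with `rank_logit`, `rank_dg`,
#'   `rank_sum` columns.
#' @export
rank_candidates <- function(candidates, require_evidence = FALSE) {
  candidates <- as_tibble(candidates)
  if (require_evidence) candidates <- filter(candidates, .data$evidence)
  if (!nrow(candidates)) abort("no candidates left to rank.")
  candidates |>
    mutate(
      rank_logit = rank(-.data$logit_prob, ties.method = "min"),
      rank_dg = rank(.data$dg_hybrid, ties.method = "min"),
      rank_sum = .data$rank_logit + .data$rank_dg
    ) |>
    arrange(.data$rank_sum, dplyr::desc(.data$logit_prob), .data$mirna)
}

#' @rdname rank_candidates
#' @return For `select_best()`: the single best candidate (one-row tibble).
#' @export
select_best <- function(candidates, require_evidence = FALSE) {
  slice_head(rank_candidates(candidates, require_evidence), n = 1L)
}

#' Plot an accessibility profile with regions and candidate sites
#'
#' @param profile An `accessibility_profile`.
#' @param regions Optional region tibble to shade.
#' @param candidates Optional candidate-site tibble to mark.
#' @param threshold Threshold line. Default 0.5.
#' @return A ggplot object.
#' @export
plot_accessibility <- function(profile, regions = NULL, candidates = NULL,
                               threshold = 0.5) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$position, y = .data$probability)) +
    ggplot2::geom_col(width = 1, fill = "#8661a8") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "3'UTR position (nt)",
                  y = "single-strandedness probability") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions)) {
    p <- p + ggplot2::annotate("rect", xmin = regions$start - 0.5,
                               xmax = regions$end + 0.5, ymin = 0, ymax = 1,
                               alpha = 0.15, fill = "#2c7fb8")
  }
  if (!is.null(candidates) && nrow(candidates)) {
    p <- p + ggplot2::annotate("segment", x = candidates$site_start,
                               xend = candidates$site_end,
                               y = 1.02, yend = 1.02,
                               linewidth = 2, colour = "#31a354")
  }
  p
}
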