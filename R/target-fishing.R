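#' Substring-hash structural fingerprint
#'
#' Hashes every contiguous substring of a structure string (e.g. a SMILES) of
#' length 1 to `max_substring` into a fixed-width bit set. This is a simple,
#' fully deterministic stand-in for a cheminformatics path fingerprint: two
#' structures sharing many substrings share many bits, so Tanimoto similarity
#' on these bit sets behaves like a structural similarity. Precomputed
#' fingerprints from an external cheminformatics backend can be supplied
#' anywhere a `mf_fingerprint` is accepted, via [new_fingerprint()].
#'
#' The hash is a base-31 polynomial over the substring's integer character
#' codes, accumulated modulo the prime 16777213 (the largest prime below
#' 2^24, so all intermediate products stay exactly representable as doubles),
#' then reduced modulo `width`. It is stable across platforms and R versions.
#'
#' @param structure Non-empty structure string (SMILES or any line notation).
#' @param width Fingerprint width in bits. Default 2048.
#' @param max_substring Longest substring hashed. Default 8.
#'
#' @return A `mf_fingerprint`: list with integer `bits` (sorted, unique,
#'   in `[0, width)`) and `width`.
#' @export
#' @examples
#' fp <- fingerprint("CCO")
#' tanimoto(fp, fingerprint("CCO"))
fingerprint <- function(structure, width = 2048L, max_substring = 8L) {
  if (!is.character(structure) || length(structure) != 1L || is.na(structure) ||
      nchar(structure) == 0L) {
    abort("`structure` must be a single non-empty string.")
  }
  width <- assert_count(width, "width", min = 1L)
  max_substring <- assert_count(max_substring, "max_substring", min = 1L)

  codes <- utf8ToInt(structure)
  n <- length(codes)
  bits <- integer(0)
  for (start in seq_len(n)) {
    h <- 0
    for (end in start:min(n, start + max_substring - 1L)) {
      # base-31 polynomial hash mod prime 16777213; exact in double arithmetic
      h <- (h * 31 + codes[[end]]) %% 16777213
      bits <- c(bits, as.integer(h %% width))
    }
  }
  new_fingerprint(bits, width)
}

#' Construct a fingerprint from explicit bit indices
#'
#' @param bits Integer vector of set-bit indices in `[0, width)`.
#' @param width Fingerprint width in bits.
#' @return A `mf_fingerprint` object.
#' @export
new_fingerprint <- function(bits, width = 2048L) {
  width <- assert_count(width, "width", min = 1L)
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 0L || max(bits) >= width)) {
    abort("fingerprint bit indices must lie in [0, width).")
  }
  structure(list(bits = bits, width = width), class = "mf_fingerprint")
}

#' @export
print.mf_fingerprint <- function(x, ...) {
  cat(sprintf("<mf_fingerprint: %d/%d bits set>\n", length(x$bits), x$width))
  invisible(x)
}

#' Tanimoto (Jaccard) similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over set bits. Two empty fingerprints have
#' similarity 0 by convention, so structureless inputs never count as matches.
#'
#' @param a,b `mf_fingerprint` objects of equal width.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (!inherits(a, "mf_fingerprint") || !inherits(b, "mf_fingerprint")) {
    abort("`a` and `b` must be mf_fingerprint objects.")
  }
  if (a$width != b$width) {
    abort(sprintf("fingerprint width mismatch (%d vs %d).", a$width, b$width))
  }
  union_n <- length(union(a$bits, b$bits))
  if (union_n == 0L) return(0)
  length(intersect(a$bits, b$bits)) / union_n
}

#' Read a compound library table
#'
#' Expects a CSV with columns `compound_id, structure, target_id, target_name,
#' organism, potency_um` (potency in micromolar; blank for unknown).
#'
#' @param path Path to the CSV file.
#' @return A tibble with those columns.
#' @export
read_compound_library <- function(path) {
  lib <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("compound_id", "structure", "target_id", "target_name",
                "organism", "potency_um")
  missing <- setdiff(required, names(lib))
  if (length(missing)) {
    abort(paste0("compound library is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(!is.na(lib$potency_um) & lib$potency_um <= 0)) {
    abort("`potency_um` must be positive when present.")
  }
  as_tibble(lib[required])
}

#' Ligand-based target fishing
#'
#' Finds library compounds structurally similar to the query and collects
#' their protein targets under potency and organism filters: a record
#' contributes its target when its Tanimoto similarity to the query is
#' strictly greater than `sim_min`, its potency is strictly below
#' `potency_max_um`, and its organism matches. Records with missing potency
#' are excluded (the potency criterion cannot be verified for them). Both
#' inequalities are strict, so a compound at exactly 70% similarity or
#' exactly 150 uM potency is not kept.
#'
#' @param library A compound-library tibble (see [read_compound_library()]).
#' @param query A `mf_fingerprint` for the query compound, or a structure
#'   string which is fingerprinted with defaults.
#' @param sim_min Similarity threshold (strict). Default 0.7.
#' @param potency_max_um Potency ceiling in micromolar (strict). Default 150.
#' @param organism Required organism. Default `"Homo sapiens"`.
#'
#' @return A tibble with one row per distinct target: `target_id`,
#'   `target_name`, `n_compounds`, `best_similarity`, and `compound_ids`
#'   (list-column of contributing compound ids — the provenance trail).
#' @export
fish_targets <- function(library, query, sim_min = 0.7, potency_max_um = 150,
                         organism = "Homo sapiens") {
  if (!is.data.frame(library) || nrow(library) == 0L) {
    abort("`library` must be a non-empty data frame.")
  }
  if (is.character(query)) query <- fingerprint(query)
  assert_probability(sim_min, "sim_min")
  assert_scalar_number(potency_max_um, "potency_max_um")

  org <- organism
  lib <- as_tibble(library)
  lib$.similarity <- purrr::map_dbl(lib$structure, function(s) {
    tanimoto(query, fingerprint(s, width = query$width))
  })
  hits <- lib |>
    filter(
      .data$.similarity > sim_min,
      !is.na(.data$potency_um), .data$potency_um < potency_max_um,
      .data$organism == org
    )
  if (!nrow(hits)) {
    return(tibble(target_id = character(0), target_name = character(0),
                  n_compounds = integer(0), best_similarity = numeric(0),
                  compound_ids = list()))
  }
  hits |>
    group_by(.data$target_id, .data$target_name) |>
    summarise(
      n_compounds = dplyr::n_distinct(.data$compound_id),
      best_similarity = max(.data$.similarity),
      compound_ids = list(sort(unique(.data$compound_id))),
      .groups = "drop"
    ) |>
    arrange(dplyr::desc(.data$best_similarity), .data$target_id)
}
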