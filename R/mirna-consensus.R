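#' Tools and score thresholds for the miRNA prediction consensus
#'
#' The four supported predictors and the filter each must pass. The rules
#' honour their usual reporting conventions exactly, including strictness:
#' * `rna22`     — binding p-value strictly below 0.05;
#' * `mirdb`     — prediction score strictly above 80;
#' * `diana`     — miTG score at or above 0.7;
#' * `targetscan`— context+ score at or below -0.1 **or** PCT at or
#'   above 0.5 (a disjunction: either branch admits the miRNA).
#'
#' @return Character vector of the four tool names.
#' @export
consensus_tools <- function() c("diana", "mirdb", "targetscan", "rna22")

# packaged column-name mapping for each tool's export dialect
tool_column_map <- function() {
  yaml::read_yaml(extdata_path("tool_columns.yml"))
}

#' Read one predictor's export table
#'
#' Column names differ between predictor exports; they are mapped onto the
#' package's canonical schema (`mirna`, `gene`, score fields, optional
#' `site_start`/`site_end`) via the packaged `tool_columns.yml` config,
#' which can be overridden without code changes. miRNA identifiers are
#' normalized to lower-case with the `hsa-` prefix ensured, so exports that
#' drop the species prefix still merge.
#'
#' @param path CSV or TSV export file (delimiter sniffed from the header).
#' @param tool One of `consensus_tools()`.
#' @param column_map Optional replacement for the packaged mapping: a named
#'   list `canonical_name = exported_name` for this tool.
#' @return A tibble of `prediction_record`s with a `tool` column.
#' @export
read_prediction_table <- function(path, tool, column_map = NULL) {
  tool <- match.arg(tool, consensus_tools())
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  map <- column_map %||% tool_column_map()[[tool]]

  header <- readr::read_lines(path, n_max = 1L, progress = FALSE)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)

  missing <- setdiff(unlist(map), names(raw))
  if (length(missing)) {
    abort(sprintf("%s table is missing mapped column(s): %s",
                  tool, paste(missing, collapse = ", ")))
  }
  out <- as_tibble(setNames(
    lapply(names(map), function(canon) raw[[map[[canon]]]]),
    names(map)
  ))
  out$tool <- tool
  out$mirna <- normalize_mirna_id(out$mirna)
  select(out, "tool", dplyr::everything())
}

#' Normalize miRNA identifiers
#'
#' Case-insensitive canonicalization with the `hsa-` species prefix ensured
#' and the conventional `miR` capitalization restored, so `MiR-181b-5p`,
#' `mir-181b-5p` and `hsa-miR-181b-5p` all map to `hsa-miR-181b-5p`.
#'
#' @param x Character vector of miRNA ids.
#' @return Normalized ids.
#' @export
normalize_mirna_id <- function(x) {
  x <- tolower(trimws(x))
  x <- ifelse(stringr::str_starts(x, "hsa-"), x, paste0("hsa-", x))
  sub("^hsa-mir-", "hsa-miR-", x)
}

#' Apply each tool's score filter
#'
#' Each miRNA is judged on its best record per tool (tools report multiple
#' sites per miRNA; the consensus treats miRNAs as units): maximum
#' `prediction_score` / `mitg_score` / `pct`, minimum `p_value` /
#' `context_plus`. Records missing their tool's required score field are
#' skipped with a warning that reports the count.
#'
#' @param records A tibble of prediction records (rows from
#'   [read_prediction_table()], possibly several tools bound together).
#' @param thresholds Named list overriding any of `rna22_p`, `mirdb_score`,
#'   `diana_mitg`, `targetscan_context`, `targetscan_pct`.
#' @return Named list `tool -> character vector` of passing miRNA ids.
#' @export
apply_tool_filters <- function(records, thresholds = list()) {
  records <- as_tibble(records)
  th <- utils::modifyList(list(
    rna22_p = 0.05, mirdb_score = 80, diana_mitg = 0.7,
    targetscan_context = -0.1, targetscan_pct = 0.5
  ), thresholds)

  required <- list(
    diana = "mitg_score", mirdb = "prediction_score",
    targetscan = c("context_plus", "pct"), rna22 = "p_value"
  )

  pass <- list()
  for (tool in consensus_tools()) {
    rows <- filter(records, .data$tool == !!tool)
    if (!nrow(rows)) {
      pass[[tool]] <- character(0)
      next
    }
    fields <- required[[tool]]
    present <- fields[fields %in% names(rows)]
    if (!length(present)) {
      warn(sprintf("%s: no required score field present; %d record(s) skipped.",
                   tool, nrow(rows)))
      pass[[tool]] <- character(0)
      next
    }
    if (length(present) == 1L) {
      bad <- is.na(rows[[present]])
      if (any(bad)) {
        warn(sprintf("%s: %d record(s) missing %s skipped.",
                     tool, sum(bad), present))
        rows <- rows[!bad, ]
      }
    }
    # drop other tools' all-NA score columns picked up by row binding
    rows <- select(rows, dplyr::any_of(c("mirna", present)))
    best <- rows |>
      group_by(.data$mirna) |>
      summarise(dplyr::across(dplyr::any_of(
        c("mitg_score", "prediction_score", "pct")), ~max(.x, na.rm = TRUE)),
        dplyr::across(dplyr::any_of(
          c("p_value", "context_plus")), ~min(.x, na.rm = TRUE)),
        .groups = "drop")
    keep <- switch(tool,
      diana = best$mitg_score >= th$diana_mitg,
      mirdb = best$prediction_score > th$mirdb_score,
      rna22 = best$p_value < th$rna22_p,
      targetscan = {
        ctx <- if ("context_plus" %in% names(best)) best$context_plus else NA_real_
        pct <- if ("pct" %in% names(best)) best$pct else NA_real_
        (!is.na(ctx) & ctx <= th$targetscan_context) |
          (!is.na(pct) & pct >= th$targetscan_pct)
      }
    )
    pass[[tool]] <- sort(best$mirna[keep & !is.na(keep)])
  }
  pass
}

#' Multi-tool consensus of miRNA predictions
#'
#' A miRNA is kept when it passes the score filter of at least `min_tools`
#' of the four predictors. The full Venn decomposition over the 15
#' non-empty tool subsets is reported: each miRNA is counted once, in the
#' cell of its exact tool membership, so the cells are disjoint and sum to
#' the union of all pass sets.
#'
#' @param pass_sets Named list `tool -> ids`, as from [apply_tool_filters()].
#' @param min_tools Minimum number of supporting tools. Default 3.
#' @return A `consensus_result`: list with `kept` (sorted ids), `venn`
#'   (tibble `tools`, `n_tools`, `n`, `mirnas`), `per_tool_pass`, and
#'   `min_tools`.
#' @export
consensus <- function(pass_sets, min_tools = 3L) {
  if (!setequal(names(pass_sets), consensus_tools())) {
    abort("`pass_sets` must be keyed by exactly the four consensus tools.")
  }
  min_tools <- assert_count(min_tools, "min_tools", min = 1L)
  pass_sets <- pass_sets[consensus_tools()]

  ids <- sort(unique(unlist(pass_sets)))
  membership <- vapply(pass_sets, function(s) ids %in% s,
                       logical(length(ids)))
  if (length(ids) == 1L) membership <- matrix(membership, nrow = 1L,
                                              dimnames = list(NULL, names(pass_sets)))
  support <- if (length(ids)) rowSums(membership) else integer(0)
  kept <- ids[support >= min_tools]

  subsets <- unlist(lapply(1:4, function(k) {
    utils::combn(consensus_tools(), k, paste, collapse = "+", simplify = FALSE)
  }))
  cell_of <- vapply(seq_along(ids), function(i) {
    paste(consensus_tools()[membership[i, ]], collapse = "+")
  }, character(1))
  venn <- tibble(
    tools = subsets,
    n_tools = stringr::str_count(subsets, stringr::fixed("+")) + 1L,
    n = unname(vapply(subsets, function(s) sum(cell_of == s), integer(1))),
    mirnas = lapply(subsets, function(s) ids[cell_of == s])
  )

  structure(
    list(kept = kept, venn = venn, per_tool_pass = pass_sets,
         min_tools = min_tools),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result: %d miRNA(s) kept by >= %d of 4 tools; union %d>\n",
              length(x$kept), x$min_tools, sum(x$venn$n)))
  invisible(x)
}

#' @export
tidy.consensus_result <- function(x, ...) {
  ids <- sort(unique(unlist(x$per_tool_pass)))
  tibble(
    mirna = ids,
    tools = unname(vapply(ids, function(id) {
      paste(names(x$per_tool_pass)[vapply(x$per_tool_pass, function(s)
        id %in% s, logical(1))], collapse = "+")
    }, character(1))),
    n_tools = unname(vapply(ids, function(id) {
      sum(vapply(x$per_tool_pass, function(s) id %in% s, logical(1)))
    }, integer(1))),
    kept = ids %in% x$kept
  )
}

#' @export
glance.consensus_result <- function(x, ...) {
  tibble(
    n_kept = length(x$kept),
    n_union = sum(x$venn$n),
    n_all_four = x$venn$n[x$venn$n_tools == 4L],
    min_tools = x$min_tools
  )
}

#' @describeIn consensus bar chart of the non-empty Venn cells.
#' @param object A `consensus_result`.
#' @param ... Ignored.
#' @export
autoplot.consensus_result <- function(object, ...) {
  dat <- filter(object$venn, .data$n > 0L) |>
    mutate(kept = .data$n_tools >= object$min_tools)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$tools, .data$n), y = .data$n, fill = .data$kept
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "tool combination", y = "miRNAs",
                  fill = sprintf(">= %d tools", object$min_tools),
                  title = "Prediction-tool consensus (disjoint Venn cells)") +
    ggplot2::theme_minimal()
}
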