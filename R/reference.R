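#' Choose the primary reference sample
#'
#' The primary reference is the sample carrying the most unique cell types;
#' ties are broken by larger cell count, then by input order. A user-chosen
#' sample id overrides the rule.
#'
#' @param cells A labeled cell collection.
#' @param choice Optional sample id to force.
#' @return A single sample id.
#' @export
select_primary <- function(cells, choice = NULL) {
  cells <- as_cell_collection(cells)
  ids <- sample_ids(cells)
  if (!is.null(choice)) {
    if (!choice %in% ids) {
      rlang::abort(paste0("reference '", choice, "' is not a sample id"))
    }
    return(choice)
  }
  require_labels(cells)
  stats <- cells |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_types = dplyr::n_distinct(.data$cell_type[!is.na(.data$cell_type)]),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(order = match(.data$sample_id, ids)) |>
    dplyr::arrange(dplyr::desc(.data$n_types), dplyr::desc(.data$n),
                   .data$order)
  stats$sample_id[1]
}

#' Choose a minimal ordered set of secondary references
#'
#' Greedy set cover over the cell types missing from the primary: repeatedly
#' pick the sample covering the most still-uncovered types (ties: larger
#' cell count, then input order). Returns an empty vector when the primary
#' already covers every type; the union of primary and secondaries always
#' covers the collection's full type set.
#'
#' @param cells A labeled cell collection.
#' @param primary The primary reference sample id (see [select_primary()]).
#' @return Character vector of sample ids, in chaining order.
#' @export
select_secondary <- function(cells, primary) {
  cells <- as_cell_collection(cells)
  require_labels(cells)
  ids <- sample_ids(cells)
  if (!primary %in% ids) rlang::abort("primary is not a sample id")
  type_sets <- split(cells$cell_type[!is.na(cells$cell_type)],
                     cells$sample_id[!is.na(cells$cell_type)])
  type_sets <- lapply(type_sets, unique)
  sizes <- table(cells$sample_id)
  uncovered <- setdiff(unique(unlist(type_sets)), type_sets[[primary]])
  candidates <- setdiff(ids, primary)
  out <- character(0)
  while (length(uncovered) > 0) {
    gain <- vapply(candidates,
                   function(s) length(intersect(type_sets[[s]], uncovered)),
                   1L)
    best <- candidates[order(-gain, -as.integer(sizes[candidates]),
                             match(candidates, ids))][1]
    if (gain[best] == 0) {
      rlang::abort("no sample covers the remaining cell types") # unreachable
    }
    out <- c(out, best)
    uncovered <- setdiff(uncovered, type_sets[[best]])
    candidates <- setdiff(candidates, best)
  }
  out
}

require_labels <- function(cells) {
  bad <- cells |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ok = any(!is.na(.data$cell_type)), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    rlang::abort(paste0(
      "sample(s) without annotations: ",
      paste(bad$sample_id, collapse = ", "),
      "; supply an annotation or run auto_annotate()"
    ))
  }
  invisible(cells)
}
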