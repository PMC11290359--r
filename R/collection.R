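#' Cell collections
#'
#' A *cell collection* is the package's central data structure: a tibble with
#' one row per cell and columns
#' \describe{
#'   \item{`sample_id`}{character, which sample the cell belongs to}
#'   \item{`cell_id`}{character, unique within its sample}
#'   \item{`cell_type`}{character annotation, possibly `NA` for unlabeled
#'     cells (or entirely `NA` when no annotation exists)}
#'   \item{`pca`}{a numeric matrix column, one row of PCA coordinates per
#'     cell; every sample must share the same number of components}
#' }
#' All user-facing verbs take such a tibble first, so calls chain with the
#' pipe. `as_cell_collection()` validates (and lightly coerces) a data frame
#' into this shape.
#'
#' @param x A data frame with the columns described above.
#' @return `x` as a validated tibble.
#' @examples
#' cells <- simulate_samples(n_samples = 2, n_cells = 50, seed = 1)
#' as_cell_collection(cells)
#' @export
as_cell_collection <- function(x) {
  if (!is.data.frame(x)) {
    rlang::abort("a cell collection must be a data frame")
  }
  x <- tibble::as_tibble(x)
  needed <- c("sample_id", "cell_id", "pca")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!("cell_type" %in% names(x))) x$cell_type <- NA_character_
  x$sample_id <- as.character(x$sample_id)
  x$cell_id <- as.character(x$cell_id)
  x$cell_type <- as.character(x$cell_type)
  if (!is.matrix(x$pca) || !is.numeric(x$pca)) {
    rlang::abort("`pca` must be a numeric matrix column")
  }
  if (nrow(x) < 1L) rlang::abort("a cell collection needs at least one cell")
  if (ncol(x$pca) < 2L) {
    rlang::abort("PCA matrices need at least 2 components")
  }
  if (any(!is.finite(x$pca))) {
    rlang::abort("`pca` contains non-finite values")
  }
  dup <- x |>
    dplyr::count(.data$sample_id, .data$cell_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    rlang::abort("cell ids must be unique within each sample")
  }
  x
}

#' @rdname as_cell_collection
#' @export
sample_ids <- function(x) unique(x$sample_id)

# pca matrix of one sample, rows in cell order
sample_pca <- function(cells, sample) {
  sel <- cells$sample_id == sample
  if (!any(sel)) rlang::abort(paste0("unknown sample: ", sample))
  cells$pca[sel, , drop = FALSE]
}

sample_labels <- function(cells, sample) {
  cells$cell_type[cells$sample_id == sample]
}

#' Which cell types does each sample carry?
#'
#' @param cells A cell collection (see [as_cell_collection()]).
#' @return A tibble with one row per (sample, cell type) pair.
#' @export
sample_types <- function(cells) {
  cells <- as_cell_collection(cells)
  cells |>
    dplyr::filter(!is.na(.data$cell_type)) |>
    dplyr::distinct(.data$sample_id, .data$cell_type) |>
    dplyr::arrange(.data$sample_id, .data$cell_type)
}

#' Integer-encode cell-type annotations across samples
#'
#' The shared vocabulary is the lexicographically sorted union of names over
#' all samples, so a given name maps to the same non-negative code in every
#' sample regardless of sample order. Decoding restores the input exactly.
#'
#' @param raw_labels A list with one character vector of labels per sample.
#' @return A list with `vocabulary` (sorted unique names) and `codes`
#'   (a list of integer vectors, 0-based, parallel to `raw_labels`).
#' @examples
#' encode_annotations(list(c("T", "B", "T"), c("NK", "T")))
#' @export
encode_annotations <- function(raw_labels) {
  if (!is.list(raw_labels)) raw_labels <- list(raw_labels)
  if (length(raw_labels) == 0 || any(vapply(raw_labels, length, 1L) == 0)) {
    rlang::abort("label lists must be non-empty")
  }
  all_labels <- unlist(raw_labels, use.names = FALSE)
  if (any(!is.na(all_labels) & all_labels == "")) {
    rlang::abort("empty-string labels are not valid annotations")
  }
  vocabulary <- sort(unique(all_labels[!is.na(all_labels)]))
  codes <- purrr::map(raw_labels, function(v) {
    match(v, vocabulary) - 1L
  })
  list(vocabulary = vocabulary, codes = codes)
}

#' @rdname encode_annotations
#' @param vocabulary The vocabulary returned by `encode_annotations()`.
#' @param codes One integer vector of 0-based codes.
#' @export
decode_annotations <- function(codes, vocabulary) {
  vocabulary[codes + 1L]
}

#' Read single-cell samples into a cell collection
#'
#' Each path is either an HDF5 single-cell container in the `.h5ad` dialect
#' (PCA matrix under `obsm/X_pca`, annotations from the named `obs` column;
#' requires the \pkg{rhdf5} package) or a delimited matrix file (`.csv` /
#' `.tsv`, cells in rows). For delimited files, labels are looked up in a
#' sidecar file `<stem>_<annotation_key>.txt` holding one label per line.
#'
#' @param paths Character vector of file paths; names, if given, become the
#'   sample ids (default: file stem).
#' @param annotation_key Name of the cell-metadata column holding the
#'   annotation, or `NULL` for unannotated input. The key must be present in
#'   every file or in none.
#' @return A cell collection tibble (see [as_cell_collection()]).
#' @export
read_samples <- function(paths, annotation_key = NULL) {
  if (length(paths) < 1) rlang::abort("need at least one input path")
  ids <- names(paths)
  if (is.null(ids)) {
    ids <- tools::file_path_sans_ext(basename(paths))
  }
  if (anyDuplicated(ids)) rlang::abort("sample ids must be unique")

  parts <- purrr::map2(unname(paths), ids, read_one_sample,
                       annotation_key = annotation_key)

  ps <- vapply(parts, function(s) ncol(s$pca), 1L)
  if (length(unique(ps)) > 1L) {
    rlang::abort(paste0(
      "samples disagree on the number of PCA components: ",
      paste(unique(ps), collapse = " vs ")
    ))
  }
  has_lab <- vapply(parts, function(s) !is.null(s$labels), TRUE)
  if (!is.null(annotation_key) && any(has_lab) && !all(has_lab)) {
    rlang::abort(paste0(
      "annotation key '", annotation_key,
      "' is present in some inputs but not all"
    ))
  }
  cells <- purrr::map_dfr(parts, function(s) {
    tibble::tibble(
      sample_id = s$sample_id,
      cell_id = s$cell_ids,
      cell_type = if (is.null(s$labels)) NA_character_ else s$labels,
      pca = s$pca
    )
  })
  as_cell_collection(cells)
}

read_one_sample <- function(path, sample_id, annotation_key = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5ad", "h5")) {
    read_sample_h5ad(path, sample_id, annotation_key)
  } else if (ext %in% c("csv", "tsv", "txt")) {
    read_sample_delim(path, sample_id, annotation_key)
  } else {
    rlang::abort(paste0("unsupported input format: .", ext))
  }
}

read_sample_h5ad <- function(path, sample_id, annotation_key = NULL) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    rlang::abort("reading .h5ad containers requires the rhdf5 package")
  }
  contents <- rhdf5::h5ls(path)
  slots <- paste0(contents$group, "/", contents$name)
  if (!any(slots %in% c("/obsm/X_pca", "obsm/X_pca"))) {
    rlang::abort(paste0("no PCA matrix under obsm/X_pca in ", path))
  }
  pca <- rhdf5::h5read(path, "obsm/X_pca")
  # h5ad stores cells x components row-major; rhdf5 returns the transpose
  pca <- t(pca)
  n <- nrow(pca)
  cell_ids <- read_h5ad_obs_column(path, slots, "_index", n)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  labels <- NULL
  if (!is.null(annotation_key)) {
    labels <- read_h5ad_obs_column(path, slots, annotation_key, n)
  }
  list(sample_id = sample_id, cell_ids = as.character(cell_ids),
       pca = pca, labels = labels)
}

# obs columns are either plain arrays or encoded categoricals
# (group with `categories` + `codes`)
read_h5ad_obs_column <- function(path, slots, key, n) {
  plain <- paste0("/obs/", key)
  if (plain %in% slots) {
    grp <- paste0("/obs/", key, "/codes")
    if (grp %in% slots) {
      codes <- as.integer(rhdf5::h5read(path, paste0("obs/", key, "/codes")))
      cats <- as.character(rhdf5::h5read(path, paste0("obs/", key, "/categories")))
      out <- ifelse(codes < 0, NA_character_, cats[codes + 1L])
      return(out)
    }
    return(as.character(rhdf5::h5read(path, paste0("obs/", key))))
  }
  NULL
}

read_sample_delim <- function(path, sample_id, annotation_key = NULL) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- which(names(tab) %in% c("cell_id", ""))[1]
  if (!is.na(id_col) && !is.numeric(tab[[id_col]])) {
    cell_ids <- as.character(tab[[id_col]])
    tab <- tab[, -id_col, drop = FALSE]
  } else {
    cell_ids <- paste0("cell_", seq_len(nrow(tab)))
  }
  if (!all(vapply(tab, is.numeric, TRUE))) {
    rlang::abort(paste0(path, " does not look like a numeric PCA matrix"))
  }
  pca <- as.matrix(tab)
  dimnames(pca) <- NULL
  labels <- NULL
  if (!is.null(annotation_key)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), "_", annotation_key, ".txt")
    if (file.exists(sidecar)) {
      labels <- readLines(sidecar)
      if (length(labels) != nrow(pca)) {
        rlang::abort(paste0("label file ", sidecar,
                            " has ", length(labels), " lines for ",
                            nrow(pca), " cells"))
      }
    }
  }
  list(sample_id = sample_id, cell_ids = cell_ids, pca = pca, labels = labels)
}

#' Write / read an embedding table
#'
#' Writes one row per cell (`cell_id`, `x`, `y`, `label`, `provenance`,
#' `sample_id`) as CSV at full double precision, so that reading the table
#' back reproduces the coordinates bit-exactly.
#'
#' @param embedding An embedding tibble as produced by [sne_align()] or
#'   [embed_independent()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(all(c("cell_id", "x", "y") %in% names(embedding)))
  out <- tibble::tibble(
    cell_id = embedding$cell_id,
    x = sprintf("%.17g", embedding$x),
    y = sprintf("%.17g", embedding$y),
    label = if ("cell_type" %in% names(embedding)) embedding$cell_type else NA,
    provenance = if ("provenance" %in% names(embedding)) embedding$provenance else NA,
    sample_id = if ("sample_id" %in% names(embedding)) embedding$sample_id else NA
  )
  utils::write.csv(out, path, row.names = FALSE,
                   quote = which(names(out) %in%
                                   c("cell_id", "label", "provenance",
                                     "sample_id")))
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  tab$x <- as.numeric(tab$x)
  tab$y <- as.numeric(tab$y)
  tibble::tibble(
    sample_id = as.character(tab$sample_id),
    cell_id = tab$cell_id,
    cell_type = as.character(tab$label),
    x = tab$x, y = tab$y,
    provenance = as.character(tab$provenance)
  )
}
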