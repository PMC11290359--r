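#' Softly align t-SNE embeddings across samples
#'
#' End-to-end pipeline: (annotation fallback if requested) -> reference
#' selection -> Procrustes alignment of PCA matrices on shared-type
#' centroids -> plain embedding of the primary reference -> sequential
#' force-embedding of secondary references to complete the center set ->
#' force-embedding of the remaining samples. With `lambda = 0` the force
#' step vanishes and every sample gets the aligned-initialization
#' ("primary") embedding.
#'
#' @param cells A cell collection (see [as_cell_collection()]).
#' @param reference Optional sample id to force as primary reference.
#' @param lambda Force weight (0 disables forces).
#' @param perplexity,n_iter_early,n_iter_main,exaggeration_early,learning_rate,init_std
#'   t-SNE settings, see [embed_config()].
#' @param seed Integer seed.
#' @param allow_reflection Permit reflections in the Procrustes fit.
#' @param also_independent Also compute per-sample independent embeddings
#'   (for metrics / comparison).
#' @param auto_annotate If the collection is unannotated, generate matched
#'   cluster labels first (see [auto_annotate()]); without this flag an
#'   unannotated collection is an error.
#' @param fallback_k,representatives_per_cluster,mnn_neighbors Parameters of
#'   the annotation fallback.
#' @return An object of class `sne_alignment` with elements `embeddings`
#'   (tibble over all samples), `independent` (tibble or `NULL`), `centers`,
#'   `force` (final per-type squared center distances), `procrustes`
#'   (named list of fits), `reference`, `secondaries`, `config`. Supports
#'   `tidy()`, `glance()` and `autoplot()`.
#' @examples
#' \donttest{
#' cells <- simulate_samples(n_samples = 2, n_cells = 200, seed = 1)
#' fit <- sne_align(cells, perplexity = 15, seed = 1)
#' glance(fit)
#' }
#' @export
sne_align <- function(cells, reference = NULL, lambda = 0.1, perplexity = 30,
                      n_iter_early = 0, n_iter_main = 750,
                      exaggeration_early = 12, learning_rate = "auto",
                      init_std = 1e-4, seed = 0L, allow_reflection = TRUE,
                      also_independent = FALSE, auto_annotate = FALSE,
                      fallback_k = 10, representatives_per_cluster = 20,
                      mnn_neighbors = 15) {
  cells <- as_cell_collection(cells)
  config <- embed_config(
    perplexity = perplexity, n_iter_early = n_iter_early,
    n_iter_main = n_iter_main, exaggeration_early = exaggeration_early,
    lambda = lambda, learning_rate = learning_rate, init_std = init_std,
    seed = seed
  )
  unlabeled <- all(is.na(cells$cell_type))
  if (unlabeled) {
    if (!auto_annotate) {
      rlang::abort(paste0(
        "no cell-type annotations found; supply a labeled collection or ",
        "set auto_annotate = TRUE to generate matched cluster labels"
      ))
    }
    cells <- auto_annotate(cells, reference = reference, k = fallback_k,
                           m = representatives_per_cluster,
                           n_neighbors = mnn_neighbors, seed = seed)
  }

  independent <- if (also_independent) embed_independent(cells, config) else NULL

  primary <- select_primary(cells, reference)
  secondaries <- select_secondary(cells, primary)
  aligned <- align_samples(cells, reference = primary,
                           allow_reflection = allow_reflection)

  refs <- build_reference_centers(aligned, primary, secondaries, config)
  embeddings <- refs$embeddings
  force_states <- list()
  for (s in setdiff(sample_ids(aligned), c(primary, secondaries))) {
    if (config$lambda > 0) {
      run <- embed_with_forces(aligned, s, refs$centers, config)
      embeddings[[s]] <- run$embedding
      force_states[[s]] <- run$force_state
    } else {
      pca <- sample_pca(aligned, s)
      run <- tsne_run(pca, config,
                      initialize_embedding(pca, config$init_std, config$seed))
      embeddings[[s]] <- embedding_tibble(aligned, s, run$coords, "primary",
                                          config$seed)
    }
  }
  # keep input sample order in the combined table
  embeddings <- dplyr::bind_rows(embeddings[sample_ids(aligned)])

  force <- if (length(force_states) > 0) {
    dplyr::bind_rows(force_states, .id = "sample_id")
  } else {
    tibble::tibble(sample_id = character(0), cell_type = character(0),
                   d = numeric(0))
  }

  structure(list(
    embeddings = embeddings,
    independent = independent,
    centers = refs$centers,
    force = force,
    procrustes = attr(aligned, "procrustes"),
    reference = primary,
    secondaries = secondaries,
    config = config
  ), class = "sne_alignment")
}

#' @export
print.sne_alignment <- function(x, ...) {
  ids <- unique(x$embeddings$sample_id)
  cat("Soft t-SNE alignment of", length(ids), "samples\n")
  cat("  primary reference:", x$reference,
      if (length(x$secondaries)) paste0("(secondaries: ",
                                        paste(x$secondaries, collapse = ", "),
                                        ")") else "", "\n")
  cat("  lambda:", x$config$lambda, " perplexity:", x$config$perplexity,
      " seed:", x$config$seed, "\n")
  cat("  cell types covered by reference centers:",
      nrow(x$centers), "\n")
  invisible(x)
}

#' Broom-style accessors for `sne_alignment` objects
#'
#' `tidy()` returns the per-cell embedding table; `glance()` one row per
#' sample with its provenance, Procrustes residual and final force
#' distance.
#'
#' @param x An [sne_align()] result.
#' @param ... Unused.
#' @export
tidy.sne_alignment <- function(x, ...) {
  x$embeddings
}

#' @rdname tidy.sne_alignment
#' @export
glance.sne_alignment <- function(x, ...) {
  per_sample <- x$embeddings |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n = dplyr::n(),
                     provenance = .data$provenance[1], .groups = "drop")
  sse <- purrr::map_dbl(per_sample$sample_id, function(s) {
    if (is.null(x$procrustes[[s]])) NA_real_ else x$procrustes[[s]]$sse
  })
  sum_d <- purrr::map_dbl(per_sample$sample_id, function(s) {
    d <- x$force$d[x$force$sample_id == s]
    if (length(d) == 0) NA_real_ else sum(d)
  })
  per_sample |>
    dplyr::mutate(procrustes_sse = sse, force_sum_d = sum_d,
                  reference = .data$sample_id == x$reference)
}

#' Write a machine-readable run report
#'
#' Captures the effective configuration, chosen references, per-sample
#' Procrustes SSE and final per-type force distances as JSON.
#'
#' @param x An [sne_align()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(x, path) {
  stopifnot(inherits(x, "sne_alignment"))
  report <- list(
    config = unclass(x$config),
    reference = x$reference,
    secondaries = x$secondaries,
    procrustes_sse = purrr::map(x$procrustes, function(f) {
      list(sse = f$sse, sse_before = f$sse_before,
           net_scale = f$post_scale / f$pre_scale)
    }),
    force = x$force,
    centers = x$centers
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
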