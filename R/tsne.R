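#' Embedding configuration
#'
#' Collects the t-SNE and force parameters shared by all embedding verbs.
#' Defaults: perplexity 30, 750 gradient-descent iterations, learning rate
#' `"auto"`, initialization standard deviation 1e-4, and *no* early
#' exaggeration. Every embedding here starts from an informative
#' (PCA-derived, possibly Procrustes-aligned) initialization, and early
#' exaggeration — whose purpose is to form a global layout from a random
#' start — erases exactly the structure that initialization plants;
#' established t-SNE implementations likewise disable it when an
#' initialization is supplied. Set `n_iter_early > 0` to enable an
#' exaggerated phase (factor `exaggeration_early`); forces are off during
#' that phase, and the auto learning rate then drops to
#' `n / (4 * exaggeration_early)`, the stability bound of the exaggerated
#' attraction step for the canonical factor-4 KL gradient.
#'
#' `lambda` is the weight of the center-attraction force: at each
#' main-phase iteration every shared cell type is translated by `lambda`
#' times the offset from its current embedding center to the reference
#' center, so `lambda = 0` reduces exactly to plain t-SNE and `lambda = 1`
#' snaps centers onto the reference in one step.
#'
#' @param perplexity t-SNE perplexity (effective neighbor count); must be
#'   smaller than the number of cells.
#' @param n_iter_early,n_iter_main Iteration counts for the (optional)
#'   early-exaggeration phase and the main phase.
#' @param exaggeration_early Early-exaggeration factor (used only when
#'   `n_iter_early > 0`).
#' @param lambda Non-negative force weight.
#' @param learning_rate Positive number or `"auto"` (200 without an
#'   exaggeration phase, the common exact t-SNE default; otherwise the
#'   stability bound above).
#' @param init_std Standard deviation the first initialization column is
#'   scaled to.
#' @param seed Integer seed (used only where randomness enters, e.g. the
#'   Gaussian fallback initialization); given a seed, single-threaded runs
#'   are bit-reproducible.
#' @return A list of class `embed_config`.
#' @export
embed_config <- function(perplexity = 30, n_iter_early = 0,
                         n_iter_main = 750, exaggeration_early = 12,
                         lambda = 0.1, learning_rate = "auto",
                         init_std = 1e-4, seed = 0L) {
  stopifnot(perplexity > 0, n_iter_early >= 0, n_iter_main >= 0,
            exaggeration_early >= 1, lambda >= 0, init_std > 0,
            identical(learning_rate, "auto") ||
              (is.numeric(learning_rate) && learning_rate > 0))
  structure(list(perplexity = perplexity, n_iter_early = n_iter_early,
                 n_iter_main = n_iter_main,
                 exaggeration_early = exaggeration_early, lambda = lambda,
                 learning_rate = learning_rate, init_std = init_std,
                 seed = as.integer(seed)),
            class = "embed_config")
}

as_embed_config <- function(config) {
  if (inherits(config, "embed_config")) return(config)
  do.call(embed_config, config)
}

#' PCA-derived embedding initialization
#'
#' Takes the first two columns of the (aligned) PCA matrix and rescales both
#' jointly so the first column's standard deviation equals `init_std`; using
#' the transformed components makes aligned samples start from compatible
#' layouts, and the small scale is the standard t-SNE starting regime. If
#' the first component has zero variance, a seeded Gaussian initialization
#' is used instead (with a warning).
#'
#' @param pca Numeric matrix with at least two columns.
#' @param init_std Target standard deviation of column 1.
#' @param seed Seed for the Gaussian fallback.
#' @return An `n x 2` matrix.
#' @export
initialize_embedding <- function(pca, init_std = 1e-4, seed = 0L) {
  pca <- as.matrix(pca)
  stopifnot(ncol(pca) >= 2)
  y <- pca[, 1:2, drop = FALSE]
  s <- stats::sd(y[, 1])
  if (!is.finite(s) || s == 0) {
    rlang::warn("zero-variance first component; falling back to Gaussian init")
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(as.integer(seed))
    return(matrix(stats::rnorm(2 * nrow(pca), sd = init_std), ncol = 2))
  }
  dimnames(y) <- NULL
  y * (init_std / s)
}

#' One center-attraction force step
#'
#' Translates every cell of each shared type rigidly by `lambda` times the
#' offset from the type's current embedding center to its reference center.
#' Within-type pairwise distances are unchanged; types absent from `centers`
#' are left untouched. Iterating this step alone shrinks the summed squared
#' center distance geometrically by `(1 - lambda)^2` per step.
#'
#' @param coords `n x 2` embedding coordinates.
#' @param labels Cell types, length `n` (`NA` = no force).
#' @param centers Reference centers: a tibble with columns `cell_type`,
#'   `x`, `y` (as produced by [embed_reference()]).
#' @param lambda Force weight.
#' @return Updated coordinates.
#' @export
apply_force_step <- function(coords, labels, centers, lambda) {
  stopifnot(lambda >= 0)
  if (lambda == 0) return(coords)
  labels <- as.character(labels)
  for (i in seq_len(nrow(centers))) {
    sel <- !is.na(labels) & labels == centers$cell_type[i]
    if (!any(sel)) next
    cur <- colMeans(coords[sel, , drop = FALSE])
    offset <- c(centers$x[i], centers$y[i]) - cur
    coords[sel, 1] <- coords[sel, 1] + lambda * offset[1]
    coords[sel, 2] <- coords[sel, 2] + lambda * offset[2]
  }
  coords
}

# Core gradient-descent loop: exact-gradient t-SNE with momentum and gains,
# optionally alternating each main-phase iteration with a force step.
tsne_run <- function(x, config, init, labels = NULL, centers = NULL) {
  n <- nrow(x)
  if (config$perplexity >= n) {
    rlang::abort("perplexity must be smaller than the number of cells")
  }
  p <- .tsne_affinities(as.matrix(x), config$perplexity)
  y <- init
  # Auto learning rate: 200 (the common exact t-SNE default) when there is
  # no exaggerated phase. With exaggeration on, n/(4*exaggeration): the
  # stability bound of the exaggerated attraction step for the canonical
  # factor-4 KL gradient, so the informative PCA initialization is not
  # destroyed by oscillation. (The n/exaggeration rule of implementations
  # whose gradient omits the 4, translated.)
  eta <- if (identical(config$learning_rate, "auto")) {
    if (config$n_iter_early > 0) {
      max(n / (4 * config$exaggeration_early), 2)
    } else 200
  } else config$learning_rate
  update <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  total <- config$n_iter_early + config$n_iter_main
  use_force <- !is.null(centers) && config$lambda > 0 && !is.null(labels)
  for (iter in seq_len(total)) {
    early <- iter <= config$n_iter_early
    momentum <- if (early) 0.5 else 0.8
    exagg <- if (early) config$exaggeration_early else 1
    g <- .tsne_gradient(y, p, exagg)
    same_sign <- sign(g) == sign(update)
    gains <- ifelse(same_sign, gains * 0.8, gains + 0.2)
    gains[gains < 0.01] <- 0.01
    update <- momentum * update - eta * gains * g
    y <- y + update
    if (use_force && !early) {
      y <- apply_force_step(y, labels, centers, config$lambda)
    }
  }
  list(coords = y, kl = .tsne_kl(y, p))
}

embedding_tibble <- function(cells, sample, coords, provenance, seed) {
  sel <- cells$sample_id == sample
  tibble::tibble(
    sample_id = sample,
    cell_id = cells$cell_id[sel],
    cell_type = cells$cell_type[sel],
    x = coords[, 1], y = coords[, 2],
    provenance = provenance, seed = as.integer(seed)
  )
}

#' Embed every sample independently
#'
#' Plain exact t-SNE per sample from its own (untransformed) PCA
#' initialization; the baseline that alignment is compared against.
#'
#' @param cells A cell collection.
#' @param config An [embed_config()] (or a list of its arguments).
#' @return An embedding tibble (`sample_id`, `cell_id`, `cell_type`, `x`,
#'   `y`, `provenance = "independent"`, `seed`).
#' @export
embed_independent <- function(cells, config = embed_config()) {
  cells <- as_cell_collection(cells)
  config <- as_embed_config(config)
  purrr::map_dfr(sample_ids(cells), function(s) {
    pca <- sample_pca(cells, s)
    run <- tsne_run(pca, config,
                    initialize_embedding(pca, config$init_std, config$seed))
    embedding_tibble(cells, s, run$coords, "independent", config$seed)
  })
}

#' Embed the reference sample and extract its type centers
#'
#' The reference is embedded with plain t-SNE (no forces) from its PCA
#' initialization; per-type centers of the final coordinates seed the
#' reference center set that other samples are pulled toward.
#'
#' @param cells A labeled cell collection (PCA already aligned or not; the
#'   reference is embedded as-is).
#' @param sample Reference sample id.
#' @param config An [embed_config()].
#' @return A list with `embedding` (tibble, provenance `"primary"`) and
#'   `centers` (tibble `cell_type`, `x`, `y`, `source`).
#' @export
embed_reference <- function(cells, sample, config = embed_config()) {
  cells <- as_cell_collection(cells)
  config <- as_embed_config(config)
  lab <- sample_labels(cells, sample)
  if (all(is.na(lab))) rlang::abort("reference sample must be labeled")
  pca <- sample_pca(cells, sample)
  run <- tsne_run(pca, config,
                  initialize_embedding(pca, config$init_std, config$seed))
  types <- sort(unique(stats::na.omit(lab)))
  cen <- compute_type_centers(run$coords, lab, types)
  list(
    embedding = embedding_tibble(cells, sample, run$coords, "primary",
                                 config$seed),
    centers = tibble::tibble(cell_type = types, x = cen[, 1], y = cen[, 2],
                             source = sample)
  )
}

#' Embed one sample with center-attraction forces
#'
#' Alternates each main-phase iteration between one t-SNE gradient step and
#' one force step pulling each shared cell type's embedding center toward
#' its reference center (see [apply_force_step()]). With `lambda = 0` the
#' result is element-wise identical to a plain t-SNE run from the same
#' initialization.
#'
#' @param cells A labeled cell collection (PCA aligned to the reference).
#' @param sample Sample id to embed.
#' @param centers Reference center tibble (`cell_type`, `x`, `y`).
#' @param config An [embed_config()].
#' @param warn_unshared Warn about sample types that have no reference
#'   center (suppressed internally when chaining secondary references,
#'   whose unshared types are expected).
#' @return A list with `embedding` (tibble, provenance `"force"`, or
#'   `"primary"` when `lambda = 0`) and `force_state` (tibble `cell_type`,
#'   `d` = final squared center distance, plus the shared-type count as
#'   attribute `"K"`).
#' @export
embed_with_forces <- function(cells, sample, centers,
                              config = embed_config(),
                              warn_unshared = TRUE) {
  cells <- as_cell_collection(cells)
  config <- as_embed_config(config)
  lab <- sample_labels(cells, sample)
  if (all(is.na(lab))) rlang::abort("sample must be labeled")
  shared <- intersect(unique(stats::na.omit(lab)), centers$cell_type)
  if (length(shared) == 0) {
    rlang::abort(paste0("sample ", sample,
                        " shares no cell types with the reference centers"))
  }
  extra <- setdiff(unique(stats::na.omit(lab)), centers$cell_type)
  if (length(extra) > 0 && config$lambda > 0 && warn_unshared) {
    rlang::warn(paste0("no reference center for type(s) ",
                       paste(extra, collapse = ", "),
                       " in sample ", sample, "; no force applied to them"))
  }
  pca <- sample_pca(cells, sample)
  run <- tsne_run(pca, config,
                  initialize_embedding(pca, config$init_std, config$seed),
                  labels = lab,
                  centers = centers[centers$cell_type %in% shared, ,
                                    drop = FALSE])
  shared <- sort(shared)
  cen <- compute_type_centers(run$coords, lab, shared)
  ref <- centers[match(shared, centers$cell_type), ]
  d <- (ref$x - cen[, 1])^2 + (ref$y - cen[, 2])^2
  state <- tibble::tibble(cell_type = shared, d = unname(d))
  attr(state, "K") <- length(shared)
  provenance <- if (config$lambda > 0) "force" else "primary"
  list(
    embedding = embedding_tibble(cells, sample, run$coords, provenance,
                                 config$seed),
    force_state = state
  )
}

#' Build the complete reference center set by chaining secondaries
#'
#' Starts from the primary reference's per-type embedding centers; each
#' secondary reference (in the order chosen by [select_secondary()]) is
#' embedded with forces against the current center set and contributes
#' centers for its cell types not yet present. The final map covers every
#' type in the collection.
#'
#' @param cells A labeled, aligned cell collection.
#' @param primary Primary reference sample id.
#' @param secondaries Ordered secondary reference ids (possibly empty).
#' @param config An [embed_config()].
#' @return A list with `centers` (tibble `cell_type`, `x`, `y`, `source`)
#'   and `embeddings` (named list of embedding tibbles for the reference
#'   samples, primary first).
#' @export
build_reference_centers <- function(cells, primary, secondaries = character(0),
                                    config = embed_config()) {
  cells <- as_cell_collection(cells)
  config <- as_embed_config(config)
  ref <- embed_reference(cells, primary, config)
  centers <- ref$centers
  embeddings <- stats::setNames(list(ref$embedding), primary)
  for (s in secondaries) {
    # a secondary's unshared types are expected: it exists to contribute them
    run <- embed_with_forces(cells, s, centers, config,
                             warn_unshared = FALSE)
    embeddings[[s]] <- run$embedding
    lab <- sample_labels(cells, s)
    new_types <- setdiff(unique(stats::na.omit(lab)), centers$cell_type)
    if (length(new_types) > 0) {
      cen <- compute_type_centers(
        as.matrix(run$embedding[, c("x", "y")]), lab, sort(new_types)
      )
      centers <- dplyr::bind_rows(centers, tibble::tibble(
        cell_type = rownames(cen), x = cen[, 1], y = cen[, 2], source = s
      ))
    }
  }
  list(centers = dplyr::arrange(centers, .data$cell_type),
       embeddings = embeddings)
}
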