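#' Alignment score between two embeddings
#'
#' Each embedding is first normalized on its own — centered on its grand
#' centroid and divided by the root-mean-square cell distance from it — so
#' the score ignores the arbitrary origin and scale of a t-SNE run (but not
#' its orientation). The per-type centers of the shared cell types are then
#' compared: `d` is the sum of squared Euclidean distances between matched
#' normalized centers and the score is `1 / (1 + d)`, so 1 means the shared
#' centers coincide exactly.
#'
#' @param emb_a,emb_b Embedding tibbles with columns `cell_type`, `x`, `y`
#'   (one sample each).
#' @return A single number in (0, 1].
#' @examples
#' emb <- tibble::tibble(cell_type = rep(c("a", "b"), 5),
#'                       x = rnorm(10), y = rnorm(10))
#' alignment_score(emb, emb) # == 1
#' @export
alignment_score <- function(emb_a, emb_b) {
  shared <- intersect(unique(stats::na.omit(emb_a$cell_type)),
                      unique(stats::na.omit(emb_b$cell_type)))
  if (length(shared) == 0) {
    rlang::abort("no shared cell types; alignment score undefined")
  }
  shared <- sort(shared)
  ca <- compute_type_centers(normalize_embedding(emb_a), emb_a$cell_type,
                             shared)
  cb <- compute_type_centers(normalize_embedding(emb_b), emb_b$cell_type,
                             shared)
  d <- sum((ca - cb)^2)
  1 / (1 + d)
}

# center on the grand centroid, scale by RMS radius
normalize_embedding <- function(emb) {
  m <- cbind(emb$x, emb$y)
  m <- sweep(m, 2, colMeans(m))
  r <- sqrt(mean(rowSums(m^2)))
  if (r <= 0) rlang::abort("degenerate embedding: all cells coincide")
  m / r
}

#' Pairwise alignment scores across all samples of an embedding table
#'
#' @param embeddings An embedding tibble covering several samples.
#' @return A tibble with one row per unordered sample pair and its
#'   [alignment_score()].
#' @export
alignment_scores <- function(embeddings) {
  ids <- unique(embeddings$sample_id)
  if (length(ids) < 2) rlang::abort("need at least two samples")
  pairs <- utils::combn(ids, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    tibble::tibble(
      sample_a = a, sample_b = b,
      score = alignment_score(embeddings[embeddings$sample_id == a, ],
                              embeddings[embeddings$sample_id == b, ])
    )
  })
}

#' Locality preservation between an independent and an aligned embedding
#'
#' For every cell, the `k` nearest neighbors (Euclidean, self excluded, ties
#' broken by cell index) are found in both embeddings of the same sample;
#' the preserved fraction is the size of the intersection divided by `k`.
#' The metric is invariant to any isometry or uniform scaling of either
#' embedding.
#'
#' @param emb_independent,emb_aligned Embedding tibbles holding the same
#'   cells of one sample in the same row order.
#' @param k Neighborhood size (default 30; must be `< n`).
#' @return A tibble (`sample_id`, `cell_id`, `fraction`) with attributes
#'   `"mean"` and `"sd"`; `summary()`-style access via
#'   `attr(x, "mean")` or plain `mean(x$fraction)`.
#' @export
locality_preservation <- function(emb_independent, emb_aligned, k = 30) {
  if (nrow(emb_independent) != nrow(emb_aligned) ||
      !identical(emb_independent$cell_id, emb_aligned$cell_id) ||
      !identical(emb_independent$sample_id, emb_aligned$sample_id)) {
    rlang::abort("embeddings must hold the same cells in the same order")
  }
  n <- nrow(emb_independent)
  if (k >= n) rlang::abort("k must be smaller than the number of cells")
  nn_a <- knn_indices(cbind(emb_independent$x, emb_independent$y), k)
  nn_b <- knn_indices(cbind(emb_aligned$x, emb_aligned$y), k)
  frac <- vapply(seq_len(n), function(i) {
    length(intersect(nn_a[i, ], nn_b[i, ])) / k
  }, 0)
  out <- tibble::tibble(
    sample_id = emb_independent$sample_id,
    cell_id = emb_independent$cell_id,
    fraction = frac
  )
  attr(out, "mean") <- mean(frac)
  attr(out, "sd") <- stats::sd(frac)
  out
}

# exact kNN with deterministic tie-break by index; n is small in all
# in-scope uses, so the dense distance matrix is fine
knn_indices <- function(coords, k) {
  n <- nrow(coords)
  d <- cross_sq_dist(coords, coords)
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r, seq_along(r))[seq_len(k)]))
}
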