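#' k-means cluster model on a reference sample
#'
#' Clusters one sample's PCA coordinates with k-means and records, for each
#' cluster, the `m` member cells closest to its centroid. These
#' representative cells anchor the mutual-nearest-neighbor transfer of
#' cluster identity to the other samples when no cell-type annotation
#' exists. The resulting clusters are purely for visual alignment, not for
#' biological identification.
#'
#' @param cells A cell collection.
#' @param sample Reference sample id.
#' @param k Number of clusters (must not exceed the sample's cell count).
#' @param m Representative cells per cluster.
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return A list of class `cluster_model`: `k`, `centroids` (`k x P`),
#'   `reference_sample_id`, `labels` (cluster names per reference cell), and
#'   `representatives` (per cluster, the indices of its `m` nearest cells).
#' @export
kmeans_cluster_reference <- function(cells, sample, k = 10, m = 20,
                                     seed = 0L) {
  cells <- as_cell_collection(cells)
  x <- sample_pca(cells, sample)
  if (k > nrow(x)) rlang::abort("k cannot exceed the sample's cell count")
  stopifnot(k >= 1, m >= 1)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  fit <- NULL
  for (attempt in 0:4) {
    set.seed(as.integer(seed) + attempt)
    fit <- tryCatch(
      stats::kmeans(x, centers = k, iter.max = 100, nstart = 10),
      error = function(e) NULL
    )
    if (!is.null(fit) && all(fit$size > 0)) break
    fit <- NULL
  }
  if (is.null(fit)) {
    rlang::abort("k-means failed to produce k non-empty clusters")
  }
  cluster_names <- sprintf("cluster_%02d", seq_len(k))
  reps <- vector("list", k)
  for (j in seq_len(k)) {
    members <- which(fit$cluster == j)
    d2 <- rowSums(sweep(x[members, , drop = FALSE], 2,
                        fit$centers[j, ])^2)
    reps[[j]] <- members[order(d2, seq_along(members))][seq_len(min(m, length(members)))]
  }
  structure(list(
    k = k, centroids = unname(fit$centers),
    reference_sample_id = sample,
    labels = cluster_names[fit$cluster],
    representatives = stats::setNames(reps, cluster_names)
  ), class = "cluster_model")
}

#' Transfer reference cluster identity by mutual nearest neighbors
#'
#' Mutual-nearest-neighbor pairs (Euclidean, PCA space) are found between
#' the reference clusters' representative cells and all cells of the other
#' sample. Each paired cell in the other sample is seeded with the majority
#' cluster of its incident pairs; the seeded cells define per-cluster
#' centroids within the other sample, and every cell is then assigned to the
#' nearest seeded-cluster centroid. Reference clusters with no mutual pairs
#' are flagged absent (with a warning); if no cluster seeds at all, cells
#' fall back to the nearest reference centroid.
#'
#' @param model A [kmeans_cluster_reference()] fit.
#' @param cells A cell collection.
#' @param sample Sample id to label.
#' @param n_neighbors Neighborhood size for the mutual-nearest-neighbor
#'   search.
#' @return Character vector of cluster names, one per cell of `sample`, with
#'   attribute `"absent"` listing clusters that had no mutual pairs.
#' @export
match_clusters_mnn <- function(model, cells, sample, n_neighbors = 15) {
  stopifnot(inherits(model, "cluster_model"))
  cells <- as_cell_collection(cells)
  other <- sample_pca(cells, sample)
  if (ncol(other) != ncol(model$centroids)) {
    rlang::abort("samples disagree on the number of PCA components")
  }
  rep_idx <- unlist(model$representatives, use.names = FALSE)
  rep_cluster <- rep(names(model$representatives),
                     lengths(model$representatives))
  ref <- sample_pca(cells, model$reference_sample_id)[rep_idx, , drop = FALSE]

  d <- cross_sq_dist(ref, other)
  k_ref <- min(n_neighbors, ncol(d))
  k_oth <- min(n_neighbors, nrow(d))
  nn_of_ref <- t(apply(d, 1, function(r) order(r, seq_along(r))[seq_len(k_ref)]))
  nn_of_oth <- apply(d, 2, function(cc) order(cc, seq_along(cc))[seq_len(k_oth)])
  nn_of_oth <- matrix(nn_of_oth, nrow = k_oth)

  # mutual pairs: (rep i, cell j) with j in NN(i) and i in NN(j)
  votes <- vector("list", ncol(d))
  for (i in seq_len(nrow(d))) {
    for (j in nn_of_ref[i, ]) {
      if (i %in% nn_of_oth[, j]) {
        votes[[j]] <- c(votes[[j]], rep_cluster[i])
      }
    }
  }
  seeded <- which(lengths(votes) > 0)
  seed_label <- vapply(votes[seeded], majority_vote, "")

  clusters <- names(model$representatives)
  present <- intersect(clusters, unique(seed_label))
  absent <- setdiff(clusters, present)
  if (length(absent) > 0) {
    rlang::warn(paste0("cluster(s) without mutual pairs in sample ", sample,
                       ": ", paste(absent, collapse = ", ")))
  }
  if (length(present) == 0) {
    d_cen <- cross_sq_dist(model$centroids, other)
    out <- clusters[apply(d_cen, 2, which.min)]
    attr(out, "absent") <- absent
    return(out)
  }
  seed_centroids <- t(vapply(present, function(cl) {
    colMeans(other[seeded[seed_label == cl], , drop = FALSE])
  }, numeric(ncol(other))))
  d_seed <- cross_sq_dist(seed_centroids, other)
  out <- present[apply(d_seed, 2, which.min)]
  out[seeded] <- seed_label
  attr(out, "absent") <- absent
  out
}

majority_vote <- function(v) {
  tab <- sort(table(v), decreasing = TRUE)
  winners <- names(tab)[tab == tab[1]]
  sort(winners)[1] # ties broken by name for determinism
}

cross_sq_dist <- function(a, b) {
  # rows of a vs rows of b -> |a|^2 + |b|^2 - 2 a b'
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

#' Generate matched cluster annotations across samples
#'
#' Fallback for unannotated collections: k-means on a reference sample (by
#' default the largest), then mutual-nearest-neighbor transfer of the
#' cluster identities to every other sample via [match_clusters_mnn()]. The
#' labels are alignment scaffolding only — they carry no biological meaning.
#'
#' @param cells A cell collection (annotations, if any, are ignored).
#' @param reference Reference sample id; default = largest sample.
#' @param k,m,n_neighbors,seed Passed to the clustering and matching steps.
#' @return The collection with `cell_type` filled with cluster names.
#' @export
auto_annotate <- function(cells, reference = NULL, k = 10, m = 20,
                          n_neighbors = 15, seed = 0L) {
  cells <- as_cell_collection(cells)
  if (is.null(reference)) {
    sizes <- table(cells$sample_id)
    ids <- sample_ids(cells)
    reference <- ids[order(-as.integer(sizes[ids]), match(ids, ids))][1]
  }
  model <- kmeans_cluster_reference(cells, reference, k = k, m = m,
                                    seed = seed)
  cells$cell_type[cells$sample_id == reference] <- model$labels
  for (s in setdiff(sample_ids(cells), reference)) {
    lab <- match_clusters_mnn(model, cells, s, n_neighbors = n_neighbors)
    cells$cell_type[cells$sample_id == s] <- as.character(lab)
  }
  cells
}
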