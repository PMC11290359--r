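# Shared fixture builders and independent oracles used across test files.

# tiny labeled collection built by hand (no simulation)
make_tiny_collection <- function(p = 3) {
  pca1 <- matrix(c(0, 0, 10, 10, 0, 10), ncol = 2)
  pca1 <- cbind(pca1, matrix(0, nrow(pca1), p - 2))
  pca2 <- pca1 + 0.5
  tibble::tibble(
    sample_id = rep(c("a", "b"), each = 3),
    cell_id = paste0("c", 1:6),
    cell_type = rep(c("T", "B", "NK"), 2),
    pca = rbind(pca1, pca2)
  )
}

# well-separated Gaussian blobs in p dims with explicit assignment
make_blobs <- function(n_per, centers, sd = 0.2, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(j) {
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd),
                 n_per, ncol(centers)),
          2, centers[j, ], "+")
  }))
  list(x = x, assignment = rep(seq_len(k), each = n_per))
}

# brute-force group means, independent of compute_type_centers
oracle_group_means <- function(coords, labels, types) {
  out <- matrix(NA_real_, length(types), ncol(coords))
  for (i in seq_along(types)) {
    rows <- coords[labels == types[i], , drop = FALSE]
    for (j in seq_len(ncol(coords))) out[i, j] <- sum(rows[, j]) / nrow(rows)
  }
  rownames(out) <- types
  out
}

# exhaustive kNN by full pairwise distances, ties by index
oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    out[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  out
}

# brute-force alignment score: explicit normalization and per-type sums
oracle_alignment_score <- function(emb_a, emb_b) {
  norm1 <- function(e) {
    m <- cbind(e$x, e$y)
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(mean(rowSums(m^2)))
  }
  shared <- sort(intersect(unique(emb_a$cell_type), unique(emb_b$cell_type)))
  ma <- norm1(emb_a); mb <- norm1(emb_b)
  d <- 0
  for (tp in shared) {
    ca <- colMeans(ma[emb_a$cell_type == tp, , drop = FALSE])
    cb <- colMeans(mb[emb_b$cell_type == tp, , drop = FALSE])
    d <- d + sum((ca - cb)^2)
  }
  1 / (1 + d)
}

# all permutations of 1..k (k small)
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1)) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

# best accuracy of predicted cluster labels vs truth over label permutations
perm_accuracy <- function(pred, truth) {
  pl <- sort(unique(pred)); tl <- sort(unique(truth))
  k <- max(length(pl), length(tl))
  stopifnot(k <= 8)
  conf <- table(factor(pred, levels = pl), factor(truth, levels = tl))
  best <- 0
  for (p in all_perms(length(pl))) {
    hits <- 0
    for (i in seq_along(pl)) {
      j <- p[i]
      if (j <= length(tl)) hits <- hits + conf[i, j]
    }
    best <- max(best, hits)
  }
  best / length(pred)
}

# exhaustive minimum set cover over samples (oracle for select_secondary)
oracle_min_cover <- function(type_sets, primary) {
  uncovered <- setdiff(unique(unlist(type_sets)), type_sets[[primary]])
  if (length(uncovered) == 0) return(character(0))
  candidates <- setdiff(names(type_sets), primary)
  for (size in seq_along(candidates)) {
    combos <- utils::combn(candidates, size, simplify = FALSE)
    for (cmb in combos) {
      if (all(uncovered %in% unlist(type_sets[cmb]))) return(cmb)
    }
  }
  stop("no cover exists")
}

# dense-grid (plus local refinement) Procrustes SSE oracle for P = 2:
# searches rotation angle and reflection, with the per-candidate optimal scale
grid_procrustes_sse <- function(ref, smp, n_grid = 2000) {
  a0 <- scale(smp, scale = FALSE)
  a0 <- a0 / sqrt(sum(a0^2))
  b0 <- scale(ref, scale = FALSE)
  nb <- sqrt(sum(b0^2))
  b0 <- b0 / nb
  tr_of <- function(theta, refl) {
    r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    if (refl) r <- r %*% diag(c(1, -1))
    sum((a0 %*% r) * b0)
  }
  best <- Inf
  for (refl in c(FALSE, TRUE)) {
    f <- function(th) 1 - max(tr_of(th, refl), 0)^2
    grid <- seq(0, 2 * pi, length.out = n_grid)
    vals <- vapply(grid, f, 1)
    i <- which.min(vals)
    opt <- stats::optimize(f, c(grid[max(i - 1, 1)],
                                grid[min(i + 1, n_grid)]), tol = 1e-14)
    best <- min(best, opt$objective, min(vals))
  }
  best * nb^2
}

sample_pca_of <- function(cells, s) {
  cells$pca[cells$sample_id == s, , drop = FALSE]
}

sample_labels_of <- function(cells, s) {
  cells$cell_type[cells$sample_id == s]
}

# small embed config for fast unit tests
fast_config <- function(...) {
  embed_config(perplexity = 10, n_iter_early = 0, n_iter_main = 180, ...)
}
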