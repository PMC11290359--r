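#' Per-type centroid matrix
#'
#' Arithmetic mean of the coordinates of each requested cell type, one row
#' per type in the requested order. Used both in PCA space (to fit the
#' Procrustes alignment) and in embedding space (to measure and apply the
#' center-attraction force).
#'
#' @param coords Numeric matrix, one row per cell (any dimensionality).
#' @param labels Character (or factor) vector of cell types, length
#'   `nrow(coords)`; `NA` labels are excluded from every centroid.
#' @param types Which types to include, in order. Default: sorted unique
#'   non-`NA` labels.
#' @return A numeric matrix with `length(types)` rows, rownames = types.
#' @export
compute_type_centers <- function(coords, labels, types = NULL) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  stopifnot(nrow(coords) == length(labels))
  if (is.null(types)) types <- sort(unique(labels[!is.na(labels)]))
  centers <- matrix(NA_real_, length(types), ncol(coords),
                    dimnames = list(types, colnames(coords)))
  for (i in seq_along(types)) {
    sel <- !is.na(labels) & labels == types[i]
    if (!any(sel)) {
      rlang::abort(paste0("cell type '", types[i], "' has no cells"))
    }
    centers[i, ] <- colMeans(coords[sel, , drop = FALSE])
  }
  centers
}

#' Fit a scaled Procrustes transform between centroid matrices
#'
#' Finds the similarity transform (translation, positive uniform scale,
#' orthogonal rotation) minimizing the sum of squared distances between the
#' transformed sample centroids and the reference centroids, via the
#' closed-form SVD solution: both matrices are mean-centered and
#' Frobenius-normalized, the optimal rotation is `U t(V)` from the SVD of
#' the cross-product, and the optimal scale is the sum of singular values.
#' By default the rotation may include a reflection (determinant -1), since
#' PCA component signs are arbitrary across samples; set
#' `allow_reflection = FALSE` to restrict to proper rotations.
#'
#' @param reference,sample Centroid matrices with identical ordered rownames
#'   (the shared cell types) and at least two rows.
#' @param allow_reflection Permit determinant -1 solutions (default `TRUE`).
#' @return An object of class `procrustes_fit` holding `pre_shift`,
#'   `pre_scale`, `rotation`, `post_scale`, `post_shift`, the residual `sse`
#'   in the reference frame, and the shared `types`. Supports
#'   [generics::tidy()] (per-type residuals) and [generics::glance()].
#' @examples
#' ref <- matrix(rnorm(10), 5, 2, dimnames = list(letters[1:5], NULL))
#' theta <- pi / 3
#' rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
#' fit <- fit_procrustes(ref, ref %*% rot)
#' glance(fit)$sse
#' @export
fit_procrustes <- function(reference, sample, allow_reflection = TRUE) {
  reference <- as.matrix(reference)
  sample <- as.matrix(sample)
  if (nrow(reference) != nrow(sample) || ncol(reference) != ncol(sample)) {
    rlang::abort("centroid matrices must have identical shape")
  }
  if (!is.null(rownames(reference)) && !is.null(rownames(sample)) &&
      !identical(rownames(reference), rownames(sample))) {
    rlang::abort("centroid matrices must list the same types in the same order")
  }
  k <- nrow(reference)
  if (k < 2) {
    rlang::abort("need at least 2 shared cell types to fit a rotation")
  }
  mu_s <- colMeans(sample)
  mu_r <- colMeans(reference)
  a0 <- sweep(sample, 2, mu_s)
  b0 <- sweep(reference, 2, mu_r)
  norm_s <- sqrt(sum(a0^2))
  norm_r <- sqrt(sum(b0^2))
  if (norm_s <= 0 || norm_r <= 0) {
    rlang::abort("degenerate centroid matrix: all centroids coincide")
  }
  a0 <- a0 / norm_s
  b0 <- b0 / norm_r
  sv <- svd(crossprod(a0, b0))
  d_signs <- rep(1, length(sv$d))
  rot <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(rot) < 0) {
    d_signs[length(d_signs)] <- -1
    rot <- sv$u %*% diag(d_signs, length(d_signs)) %*% t(sv$v)
  }
  scale_opt <- sum(sv$d * d_signs)
  if (scale_opt <= 0) {
    rlang::warn("optimal Procrustes scale is non-positive; clamping")
    scale_opt <- .Machine$double.eps
  }
  # centered K x P centroids have rank at most min(K - 1, P); warn only when
  # the cross-product drops below even that (collinear centroids)
  expected_rank <- min(k - 1L, ncol(reference))
  if (sum(sv$d > 1e-12 * max(sv$d)) < expected_rank) {
    rlang::warn("collinear centroids; rotation is not unique")
  }
  fit <- structure(list(
    pre_shift = mu_s, pre_scale = norm_s,
    rotation = rot, opt_scale = scale_opt,
    post_scale = scale_opt * norm_r, post_shift = mu_r,
    types = rownames(reference),
    allow_reflection = allow_reflection
  ), class = "procrustes_fit")
  fitted <- apply_procrustes(fit, sample)
  fit$sse <- sum((fitted - reference)^2)
  fit$sse_before <- sum((sample - reference)^2)
  fit$residuals <- sqrt(rowSums((fitted - reference)^2))
  fit
}

#' Apply a fitted Procrustes transform to a full coordinate matrix
#'
#' Every cell is mapped by the same similarity fitted on the centroids:
#' center on the sample centroid mean, divide by its Frobenius norm, rotate,
#' rescale to the reference frame and restore the reference mean. Because
#' the map is a similarity, neighbor identities within the sample are
#' unchanged; only the embedding initialization is affected downstream.
#'
#' @param fit A `procrustes_fit`.
#' @param x Numeric matrix with the same number of columns the fit was made
#'   with.
#' @return The transformed matrix, same shape as `x`.
#' @export
apply_procrustes <- function(fit, x) {
  stopifnot(inherits(fit, "procrustes_fit"))
  x <- as.matrix(x)
  if (ncol(x) != length(fit$pre_shift)) {
    rlang::abort("dimension mismatch between transform and matrix")
  }
  y <- sweep(x, 2, fit$pre_shift) / fit$pre_scale
  y <- y %*% fit$rotation * fit$post_scale
  sweep(y, 2, fit$post_shift, "+")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("Scaled Procrustes fit on", length(x$types), "shared cell types\n")
  cat("  net scale:", format(x$post_scale / x$pre_scale, digits = 4),
      " det(rotation):", format(det(x$rotation), digits = 3), "\n")
  cat("  SSE:", format(x$sse, digits = 4),
      "(before alignment:", format(x$sse_before, digits = 4), ")\n")
  invisible(x)
}

#' @rdname fit_procrustes
#' @param x A `procrustes_fit`.
#' @param ... Unused.
#' @export
tidy.procrustes_fit <- function(x, ...) {
  tibble::tibble(cell_type = x$types, residual = unname(x$residuals))
}

#' @rdname fit_procrustes
#' @export
glance.procrustes_fit <- function(x, ...) {
  tibble::tibble(
    n_types = length(x$types),
    sse = x$sse,
    sse_before = x$sse_before,
    net_scale = x$post_scale / x$pre_scale,
    reflection = det(x$rotation) < 0
  )
}

#' Procrustes-align every sample's PCA matrix to the primary reference
#'
#' For each non-reference sample, centroids of the cell types shared with
#' the reference are computed in PCA space, a scaled Procrustes transform is
#' fitted on the two centroid matrices, and the transform is applied to the
#' sample's full PCA matrix. The reference sample is returned untouched.
#'
#' @param cells A labeled cell collection.
#' @param reference Primary reference sample id; default chosen by
#'   [select_primary()].
#' @param allow_reflection Passed to [fit_procrustes()].
#' @return The collection with transformed `pca`, plus attributes
#'   `"reference"` and `"procrustes"` (named list of fits for the
#'   non-reference samples).
#' @export
align_samples <- function(cells, reference = NULL, allow_reflection = TRUE) {
  cells <- as_cell_collection(cells)
  require_labels(cells)
  reference <- select_primary(cells, reference)
  ref_labels <- sample_labels(cells, reference)
  ref_pca <- sample_pca(cells, reference)
  fits <- list()
  for (s in setdiff(sample_ids(cells), reference)) {
    lab <- sample_labels(cells, s)
    shared <- sort(intersect(unique(stats::na.omit(lab)),
                             unique(stats::na.omit(ref_labels))))
    if (length(shared) < 2) {
      rlang::abort(paste0("sample ", s, " shares fewer than 2 cell types ",
                          "with the reference; cannot fit a rotation"))
    }
    fit <- fit_procrustes(
      compute_type_centers(ref_pca, ref_labels, shared),
      compute_type_centers(sample_pca(cells, s), lab, shared),
      allow_reflection = allow_reflection
    )
    sel <- cells$sample_id == s
    cells$pca[sel, ] <- apply_procrustes(fit, cells$pca[sel, , drop = FALSE])
    fits[[s]] <- fit
  }
  attr(cells, "reference") <- reference
  attr(cells, "procrustes") <- fits
  cells
}
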