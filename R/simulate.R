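#' Simulate multi-sample single-cell PCA data with known ground truth
#'
#' Draws every sample from a shared Gaussian mixture over cell types in PCA
#' space, then applies a per-sample batch effect: a planar rotation in the
#' first two components, a uniform scaling, a translation, and additive
#' Gaussian jitter. The first sample is left untransformed (identity batch
#' effect) so the generating frame is anchored; batch parameters for the
#' remaining samples are drawn once from the ranges below unless given
#' explicitly. Cell-type means are drawn once (seeded) with component-wise
#' spread decaying geometrically across components — mimicking how PCA
#' concentrates between-type separation in the leading components — and
#' rescaled so the closest pair of types is exactly `separation * type_sd`
#' apart.
#'
#' Defaults emulate a small multi-patient experiment: 3 samples of 1000
#' cells, 5 cell types, 10 components, within-type spread 1, between-type
#' separation 6 standard deviations, jitter 0.3. Rotations are drawn
#' uniform on (-pi/4, pi/4), scales uniform on (0.8, 1.25) and shifts from
#' N(0, 1) per component — batch effects that are substantial (rotations to
#' 45 degrees, translations about half the type separation) yet subdominant
#' to the biological structure, the regime in which cross-sample
#' mutual-nearest-neighbor correspondence in PCA space is meaningful.
#'
#' @param n_samples Number of samples.
#' @param n_cells Cells per sample (recycled to `n_samples`).
#' @param n_types Number of shared cell types.
#' @param n_pcs Number of PCA components.
#' @param type_sd Within-type standard deviation, per component.
#' @param separation Between-type mean separation in units of `type_sd`.
#' @param noise_sd Additive jitter standard deviation applied after the
#'   batch transform.
#' @param angles,scales,shifts Optional explicit batch parameters: a numeric
#'   vector of rotation angles (radians), a numeric vector of scales, and a
#'   list of length-`n_pcs` shift vectors, each of length `n_samples`.
#' @param dropout Optional named list mapping a sample id (`"S1"`, `"S2"`,
#'   ...) to cell-type names withheld from that sample.
#' @param labeled If `FALSE` the returned `cell_type` column is all `NA`
#'   (annotation-fallback testing); the generating assignment is still
#'   available as the `true_type` column.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A cell collection tibble with an extra `true_type` column and an
#'   attribute `"truth"` carrying `type_means` and the per-sample batch
#'   parameters.
#' @examples
#' cells <- simulate_samples(n_samples = 2, n_cells = 100, seed = 1)
#' dplyr::count(cells, sample_id, cell_type)
#' @export
simulate_samples <- function(n_samples = 3, n_cells = 1000, n_types = 5,
                             n_pcs = 10, type_sd = 1, separation = 6,
                             noise_sd = 0.3, angles = NULL, scales = NULL,
                             shifts = NULL, dropout = NULL, labeled = TRUE,
                             seed = 0L) {
  stopifnot(n_samples >= 1, n_types >= 2, n_pcs >= 2,
            type_sd > 0, separation > 0, noise_sd >= 0)
  n_cells <- rep_len(n_cells, n_samples)
  type_names <- paste0("type_", LETTERS[seq_len(n_types)])
  ids <- paste0("S", seq_len(n_samples))

  # Type means mimic PCA output: component-wise spread decays geometrically
  # (PCA orders components by variance, so between-type separation
  # concentrates in the leading components, which is what the PCA-based
  # embedding initialization relies on). Means are drawn once from the
  # seeded mean-generator stream, then rescaled so the *closest* pair of
  # types is exactly `separation * type_sd` apart.
  mean_rng <- get_rng_state()
  set.seed(as.integer(seed) + 1000003L)
  decay <- 0.7^(seq_len(n_pcs) - 1)
  type_means <- matrix(stats::rnorm(n_types * n_pcs), n_types, n_pcs,
                       dimnames = list(type_names, NULL))
  type_means <- sweep(type_means, 2, decay, "*")
  min_sep <- min(stats::dist(type_means))
  type_means <- type_means * (separation * type_sd / min_sep)
  restore_rng_state(mean_rng)

  if (!is.null(dropout)) {
    dropped_everywhere <- Reduce(
      intersect, lapply(ids, function(s) dropout[[s]] %||% character(0))
    )
    if (length(dropped_everywhere) > 0) {
      rlang::abort("dropout would remove a cell type from every sample")
    }
  }

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  if (is.null(angles)) {
    angles <- c(0, stats::runif(n_samples - 1, -pi / 4, pi / 4))
  }
  if (is.null(scales)) {
    scales <- c(1, stats::runif(n_samples - 1, 0.8, 1.25))
  }
  if (is.null(shifts)) {
    shifts <- c(list(rep(0, n_pcs)),
                purrr::map(seq_len(max(n_samples - 1, 0)),
                           ~ stats::rnorm(n_pcs, sd = 1)))
  }
  stopifnot(length(angles) == n_samples, length(scales) == n_samples,
            length(shifts) == n_samples)

  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    present <- setdiff(type_names, dropout[[ids[s]]])
    if (length(present) == 0) {
      rlang::abort(paste0("dropout leaves sample ", ids[s], " empty"))
    }
    lab <- sample(present, n_cells[s], replace = TRUE)
    x <- type_means[lab, , drop = FALSE] +
      matrix(stats::rnorm(n_cells[s] * n_pcs, sd = type_sd),
             n_cells[s], n_pcs)
    x <- planar_rotate(x, angles[s]) * scales[s]
    x <- sweep(x, 2, shifts[[s]], "+")
    if (noise_sd > 0) {
      x <- x + matrix(stats::rnorm(n_cells[s] * n_pcs, sd = noise_sd),
                      n_cells[s], n_pcs)
    }
    dimnames(x) <- NULL
    out[[s]] <- tibble::tibble(
      sample_id = ids[s],
      cell_id = paste0(ids[s], "_c", seq_len(n_cells[s])),
      cell_type = if (labeled) lab else NA_character_,
      true_type = lab,
      pca = x
    )
  }
  cells <- dplyr::bind_rows(out)
  attr(cells, "truth") <- list(
    type_means = type_means,
    params = tibble::tibble(sample_id = ids, angle = angles, scale = scales,
                            shift = shifts),
    type_sd = type_sd, noise_sd = noise_sd, separation = separation
  )
  as_cell_collection_keep_attrs(cells)
}

# rotation confined to components 1-2 so the batch effect is visible in the
# embedding initialization
planar_rotate <- function(x, angle) {
  if (angle == 0) return(x)
  r <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  x[, 1:2] <- x[, 1:2, drop = FALSE] %*% r
  x
}

as_cell_collection_keep_attrs <- function(cells) {
  truth <- attr(cells, "truth")
  cells <- as_cell_collection(cells)
  attr(cells, "truth") <- truth
  cells
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Randomly subsample one sample of a collection
#'
#' Emulates aligning samples of very different sizes: the named sample is
#' downsampled without replacement to `ceiling(fraction * n)` cells.
#'
#' @param cells A cell collection.
#' @param sample Sample id to subsample.
#' @param fraction Fraction of cells to retain, in (0, 1).
#' @param seed Integer seed.
#' @return The collection with the named sample reduced.
#' @export
subsample_cells <- function(cells, sample, fraction, seed = 0L) {
  cells <- as_cell_collection_keep_attrs(cells)
  stopifnot(fraction > 0, fraction < 1)
  sel <- which(cells$sample_id == sample)
  if (length(sel) == 0) rlang::abort(paste0("unknown sample: ", sample))
  keep_n <- ceiling(fraction * length(sel))
  n_types <- length(unique(stats::na.omit(cells$cell_type[sel])))
  if (keep_n < max(n_types, 1L)) {
    rlang::abort("fraction leaves fewer cells than cell types")
  }
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  keep <- sort(sample(sel, keep_n))
  out <- cells[c(setdiff(seq_len(nrow(cells)), sel), keep), ]
  out <- out[order(match(out$sample_id, unique(cells$sample_id))), ]
  attr(out, "truth") <- attr(cells, "truth")
  out
}

#' @rdname subsample_cells
#' @param n_cells Cells per sample before subsampling.
#' @param ... Passed on to [simulate_samples()] (two samples are generated).
#' @export
simulate_unbalanced_pair <- function(fraction = 0.1, n_cells = 1000,
                                     seed = 0L, ...) {
  cells <- simulate_samples(n_samples = 2, n_cells = n_cells, seed = seed, ...)
  subsample_cells(cells, "S2", fraction, seed = seed + 1L)
}
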