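test_that("PCA initialization is the rescaled first two components", {
  set.seed(1)
  x <- matrix(rnorm(50 * 6), 50, 6)
  init <- initialize_embedding(x, init_std = 1e-4)
  # closed form: columns 1-2 times init_std / sd(col 1)
  expect_equal(init, x[, 1:2] * (1e-4 / sd(x[, 1])), ignore_attr = TRUE,
               tolerance = 1e-14)
  expect_equal(sd(init[, 1]), 1e-4, tolerance = 1e-14)

  # already at target scale: returned unchanged
  x2 <- x[, 1:2] * (1e-4 / sd(x[, 1]))
  expect_equal(initialize_embedding(x2, init_std = 1e-4), x2,
               ignore_attr = TRUE, tolerance = 1e-14)

  # scale-invariance: doubling the input changes nothing
  expect_equal(initialize_embedding(2 * x), initialize_embedding(x),
               tolerance = 1e-14)

  # zero-variance first component falls back to a seeded Gaussian
  flat <- cbind(rep(1, 20), rnorm(20))
  expect_warning(i1 <- initialize_embedding(flat, seed = 3), "zero-variance")
  expect_warning(i2 <- initialize_embedding(flat, seed = 3), "zero-variance")
  expect_identical(i1, i2)
})

test_that("reference embedding separates blobs and is deterministic", {
  cells <- simulate_samples(n_samples = 1, n_cells = 150, n_types = 3,
                            seed = 2)
  cfg <- fast_config(seed = 2)
  ref1 <- embed_reference(cells, "S1", cfg)
  ref2 <- embed_reference(cells, "S1", cfg)
  expect_identical(ref1$embedding$x, ref2$embedding$x)
  expect_identical(ref1$embedding$y, ref2$embedding$y)

  # type centers sit inside their clusters: nearly every cell is nearest to
  # its own type's center, and each center's closest cell is of its type
  emb <- ref1$embedding
  cen <- ref1$centers
  d_to_centers <- vapply(seq_len(nrow(cen)), function(i) {
    sqrt((emb$x - cen$x[i])^2 + (emb$y - cen$y[i])^2)
  }, numeric(nrow(emb)))
  nearest <- cen$cell_type[apply(d_to_centers, 1, which.min)]
  expect_gte(mean(nearest == emb$cell_type), 0.95)
  for (i in seq_len(nrow(cen))) {
    expect_identical(emb$cell_type[which.min(d_to_centers[, i])],
                     cen$cell_type[i])
  }

  # perplexity must stay below n; the minimal run just above works
  tiny <- cells[1:31, ]
  expect_error(embed_reference(tiny, "S1", embed_config(perplexity = 31)),
               "perplexity")
  small <- embed_reference(tiny, "S1",
                           embed_config(perplexity = 30, n_iter_early = 5,
                                        n_iter_main = 5))
  expect_true(all(is.finite(small$embedding$x)))
})

test_that("lambda = 0 reduces exactly to the plain t-SNE run", {
  cells <- simulate_samples(n_samples = 2, n_cells = 120, n_types = 3,
                            seed = 3)
  aligned <- align_samples(cells)
  ref <- embed_reference(aligned, "S1", fast_config(seed = 3))
  plain <- embed_with_forces(aligned, "S2", ref$centers,
                             fast_config(lambda = 0, seed = 3))
  # oracle: drive the same sample through the reference path (no forces)
  oracle <- embed_reference(aligned, "S2", fast_config(seed = 3))
  expect_identical(plain$embedding$x, oracle$embedding$x)
  expect_identical(plain$embedding$y, oracle$embedding$y)
  expect_identical(plain$embedding$provenance[1], "primary")
})

test_that("a single force step translates types rigidly onto the target", {
  set.seed(4)
  coords <- matrix(rnorm(60), 30, 2)
  labels <- rep(c("a", "b", "c"), each = 10)
  centers <- tibble::tibble(cell_type = c("a", "b"), x = c(5, -5),
                            y = c(2, -2))

  # lambda = 1 with the t-SNE step disabled: centers land exactly on target
  stepped <- apply_force_step(coords, labels, centers, lambda = 1)
  expect_equal(colMeans(stepped[labels == "a", ]), c(5, 2), tolerance = 1e-12)
  expect_equal(colMeans(stepped[labels == "b", ]), c(-5, -2),
               tolerance = 1e-12)
  # type c has no center: untouched
  expect_identical(stepped[labels == "c", ], coords[labels == "c", ])

  # the step is a pure per-type translation: within-type distances unchanged
  for (tp in c("a", "b")) {
    expect_equal(as.matrix(dist(stepped[labels == tp, ])),
                 as.matrix(dist(coords[labels == tp, ])),
                 tolerance = 1e-12)
  }
})

test_that("iterated force steps shrink the center distance geometrically", {
  set.seed(5)
  coords <- matrix(rnorm(80, sd = 2), 40, 2)
  labels <- rep(c("a", "b"), each = 20)
  centers <- tibble::tibble(cell_type = c("a", "b"), x = c(4, -4),
                            y = c(1, -1))
  sum_d <- function(y) {
    cen <- compute_type_centers(y, labels, c("a", "b"))
    sum((cen - cbind(centers$x, centers$y))^2)
  }
  for (lambda in c(0.1, 0.5, 1.0)) {
    y <- coords
    d0 <- sum_d(y)
    for (j in 1:5) {
      y <- apply_force_step(y, labels, centers, lambda)
      expect_equal(sum_d(y), (1 - lambda)^(2 * j) * d0, tolerance = 1e-10)
    }
  }
})

test_that("forces pull shared centers toward the reference over a run", {
  cells <- simulate_samples(n_samples = 2, n_cells = 150, n_types = 3,
                            seed = 6)
  aligned <- align_samples(cells)
  cfg <- fast_config(seed = 6, lambda = 0.5)
  ref <- embed_reference(aligned, "S1", fast_config(seed = 6))
  forced <- embed_with_forces(aligned, "S2", ref$centers, cfg)
  free <- embed_with_forces(aligned, "S2", ref$centers,
                            fast_config(seed = 6, lambda = 0))
  # final summed center distance far below the force-free run
  d_of <- function(run) sum(run$force_state$d)
  expect_lt(d_of(forced), d_of(free))
  expect_identical(forced$embedding$provenance[1], "force")
  expect_identical(attr(forced$force_state, "K"), 3L)

  # disjoint type sets cannot be aligned
  bad_centers <- tibble::tibble(cell_type = "zz", x = 0, y = 0)
  expect_error(embed_with_forces(aligned, "S2", bad_centers, cfg),
               "no cell types")
})

test_that("secondary chaining completes the reference center set", {
  cells <- simulate_samples(
    n_samples = 3, n_cells = 150, n_types = 4, seed = 7,
    dropout = list(S1 = "type_D", S2 = "type_A", S3 = "type_B")
  )
  aligned <- align_samples(cells, reference = "S1")
  secs <- select_secondary(cells, "S1")
  out <- build_reference_centers(aligned, "S1", secs, fast_config(seed = 7))
  expect_setequal(out$centers$cell_type, paste0("type_", LETTERS[1:4]))
  expect_identical(anyDuplicated(out$centers$cell_type), 0L)
  # primary's own types keep the primary as source
  own <- out$centers[out$centers$cell_type %in% c("type_A", "type_B"), ]
  expect_true(all(own$source == "S1"))
  # the missing type was contributed by a secondary
  expect_false(out$centers$source[out$centers$cell_type == "type_D"] == "S1")

  # no secondaries: primary centers pass through unchanged
  ref <- embed_reference(aligned, "S1", fast_config(seed = 7))
  solo <- build_reference_centers(aligned, "S1", character(0),
                                  fast_config(seed = 7))
  expect_equal(dplyr::arrange(ref$centers, cell_type), solo$centers)
})
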