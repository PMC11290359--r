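planar_rot <- function(theta, p = 2) {
  r <- diag(p)
  r[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  r
}

test_that("type centers equal brute-force group means", {
  # one cell per type: centers are the cells themselves
  coords <- matrix(c(1, 2, 3, 4), 2, 2)
  cen <- compute_type_centers(coords, c("a", "b"))
  expect_equal(unname(cen), coords)

  # symmetric pair averages to the origin
  cen2 <- compute_type_centers(matrix(c(1, -1, 1, -1), 2, 2), c("t", "t"))
  expect_equal(unname(cen2), matrix(0, 1, 2))

  set.seed(5)
  coords <- matrix(rnorm(200 * 4), 200, 4)
  labels <- sample(letters[1:6], 200, replace = TRUE)
  types <- sort(unique(labels))
  expect_equal(compute_type_centers(coords, labels, types),
               oracle_group_means(coords, labels, types),
               tolerance = 1e-12)

  # missing wanted type is an error; NA labels are excluded
  expect_error(compute_type_centers(coords, labels, c("a", "zz")), "no cells")
  labna <- labels
  labna[1:50] <- NA
  expect_equal(compute_type_centers(coords, labna, "a"),
               oracle_group_means(coords[!is.na(labna), ],
                                  labna[!is.na(labna)], "a"),
               tolerance = 1e-12)
})

test_that("procrustes recovers constructed similarity transforms", {
  set.seed(2)
  ref <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(letters[1:5], NULL))

  # identity case
  fit0 <- fit_procrustes(ref, ref)
  expect_equal(fit0$sse, 0, tolerance = 1e-20)
  expect_equal(fit0$post_scale / fit0$pre_scale, 1, tolerance = 1e-10)
  expect_equal(fit0$rotation %*% t(fit0$rotation), diag(4), tolerance = 1e-8)

  # known planar rotation is inverted
  rot <- planar_rot(pi / 2, 4)
  fit1 <- fit_procrustes(ref, ref %*% rot)
  expect_lt(fit1$sse, 1e-10)
  expect_equal(fit1$rotation, t(rot), tolerance = 1e-8)

  # doubling the sample gives net scale one half
  fit2 <- fit_procrustes(ref, 2 * ref)
  expect_equal(fit2$post_scale / fit2$pre_scale, 0.5, tolerance = 1e-10)
  expect_lt(fit2$sse, 1e-10)

  # K = 1 is degenerate
  expect_error(fit_procrustes(ref[1, , drop = FALSE], ref[1, , drop = FALSE]),
               "at least 2")
})

test_that("fitted SSE beats random orthogonal transforms and the P=2 grid", {
  set.seed(7)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    p <- sample(2:5, 1)
    ref <- matrix(rnorm(k * p), k, p)
    smp <- matrix(rnorm(k * p), k, p)
    fit <- fit_procrustes(ref, smp)
    fitted_sse <- fit$sse

    a0 <- scale(smp, scale = FALSE)
    a0 <- a0 / sqrt(sum(a0^2))
    b0 <- scale(ref, scale = FALSE)
    b0 <- b0 / sqrt(sum(b0^2))
    nb <- sqrt(sum(scale(ref, scale = FALSE)^2))
    for (cand in 1:200) {
      q <- qr.Q(qr(matrix(rnorm(p * p), p)))
      s_opt <- max(sum((a0 %*% q) * b0), 0)
      cand_sse <- sum((s_opt * a0 %*% q - b0)^2) * nb^2
      expect_gte(cand_sse, fitted_sse - 1e-9)
    }
  }

  # dense angle grid in the plane (rotations and reflections)
  set.seed(8)
  ref <- matrix(rnorm(10), 5, 2)
  smp <- matrix(rnorm(10), 5, 2)
  fit <- fit_procrustes(ref, smp)
  grid_sse <- grid_procrustes_sse(ref, smp)
  expect_equal(fit$sse, grid_sse, tolerance = 1e-6)
})

test_that("applying the transform maps the full cloud consistently", {
  set.seed(3)
  cloud <- matrix(rnorm(100 * 3), 100, 3)
  labels <- rep(letters[1:5], each = 20)
  cen <- compute_type_centers(cloud, labels)

  # transform fitted on a rotated+scaled+shifted copy recovers the original
  rot <- planar_rot(1.1, 3)
  moved <- sweep(cloud %*% rot * 1.7, 2, c(5, -3, 2), "+")
  fit <- fit_procrustes(cen, compute_type_centers(moved, labels))
  expect_lt(max(abs(apply_procrustes(fit, moved) - cloud)), 1e-8)

  # identity fit returns the input
  fit_id <- fit_procrustes(cen, cen)
  expect_equal(apply_procrustes(fit_id, cloud), cloud, tolerance = 1e-10)

  # centers commute with the transform (linearity)
  got <- compute_type_centers(apply_procrustes(fit, moved), labels)
  expect_equal(got, apply_procrustes(fit, compute_type_centers(moved, labels)),
               tolerance = 1e-10)

  expect_error(apply_procrustes(fit, cloud[, 1:2]), "dimension")
})

test_that("similarity transforms preserve shape diagnostics", {
  set.seed(9)
  ref <- matrix(rnorm(12), 6, 2)
  smp <- matrix(rnorm(12), 6, 2)
  fit <- fit_procrustes(ref, smp)

  # unit-net-scale transforms are isometries
  fit_iso <- fit
  fit_iso$post_scale <- fit_iso$pre_scale
  x <- matrix(rnorm(40), 20, 2)
  expect_equal(as.matrix(dist(apply_procrustes(fit_iso, x))),
               as.matrix(dist(x)), tolerance = 1e-8)

  # re-fitting after applying is the identity
  aligned <- apply_procrustes(fit, smp)
  refit <- fit_procrustes(ref, aligned)
  expect_equal(refit$rotation %*% t(refit$rotation), diag(2),
               tolerance = 1e-8)
  expect_equal(refit$post_scale / refit$pre_scale, 1, tolerance = 1e-8)
  expect_equal(refit$sse, fit$sse, tolerance = 1e-10)

  # tidy/glance expose residuals and the reflection flag
  expect_identical(nrow(tidy(fit)), 6L)
  expect_identical(names(glance(fit)),
                   c("n_types", "sse", "sse_before", "net_scale", "reflection"))
})

test_that("reflections can be forbidden", {
  set.seed(10)
  ref <- matrix(rnorm(8), 4, 2)
  smp <- ref %*% diag(c(-1, 1)) # pure reflection
  fit_free <- fit_procrustes(ref, smp)
  expect_lt(fit_free$sse, 1e-15)
  expect_lt(det(fit_free$rotation), 0)
  fit_rot <- fit_procrustes(ref, smp, allow_reflection = FALSE)
  expect_gt(det(fit_rot$rotation), 0)
  expect_gt(fit_rot$sse, fit_free$sse)
})
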