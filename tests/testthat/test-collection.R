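test_that("annotation encoding uses the sorted shared vocabulary", {
  enc <- encode_annotations(list(c("T", "B", "T")))
  expect_identical(enc$vocabulary, c("B", "T"))
  expect_identical(enc$codes[[1]], c(1L, 0L, 1L))

  enc2 <- encode_annotations(list("A", "B"))
  expect_identical(enc2$vocabulary, c("A", "B"))
  expect_identical(enc2$codes, list(0L, 1L))

  # the same name gets the same code in every sample
  enc3 <- encode_annotations(list(c("B", "T"), c("T", "NK")))
  expect_identical(enc3$vocabulary, c("B", "NK", "T"))
  expect_identical(enc3$codes[[1]], c(0L, 2L))
  expect_identical(enc3$codes[[2]], c(2L, 1L))
})

test_that("encoding round-trips on random label lists", {
  set.seed(42)
  pool <- c("alpha", "beta", "gamma", "delta", "eps")
  for (rep in 1:20) {
    labs <- lapply(1:3, function(i) sample(pool, sample(1:30, 1), replace = TRUE))
    enc <- encode_annotations(labs)
    for (i in 1:3) {
      expect_identical(decode_annotations(enc$codes[[i]], enc$vocabulary),
                       labs[[i]])
    }
  }
})

test_that("empty-string labels are rejected", {
  expect_error(encode_annotations(list(c("T", ""))), "empty-string")
})

test_that("collection validation enforces the shared-shape invariants", {
  cells <- make_tiny_collection()
  expect_s3_class(as_cell_collection(cells), "tbl_df")
  bad <- cells
  bad$pca[2, 1] <- NA
  expect_error(as_cell_collection(bad), "non-finite")
  dup <- cells
  dup$cell_id <- rep("c1", 6)
  expect_error(as_cell_collection(dup), "unique")
  expect_error(as_cell_collection(cells[, c("sample_id", "cell_id")]),
               "missing column")
})

test_that("delimited samples read back with consistent vocabulary", {
  dir <- withr::local_tempdir()
  cells <- make_tiny_collection()
  for (s in c("a", "b")) {
    m <- cells$pca[cells$sample_id == s, ]
    df <- as.data.frame(m)
    names(df) <- paste0("PC", seq_len(ncol(m)))
    df <- cbind(cell_id = cells$cell_id[cells$sample_id == s], df)
    utils::write.csv(df, file.path(dir, paste0(s, ".csv")), row.names = FALSE)
    writeLines(cells$cell_type[cells$sample_id == s],
               file.path(dir, paste0(s, "_cell_type.txt")))
  }
  got <- read_samples(file.path(dir, c("a.csv", "b.csv")),
                      annotation_key = "cell_type")
  expect_identical(sample_ids(got), c("a", "b"))
  expect_equal(got$pca, cells$pca, ignore_attr = TRUE)
  expect_identical(got$cell_type, cells$cell_type)

  # no annotation key -> labels absent
  got2 <- read_samples(file.path(dir, c("a.csv", "b.csv")))
  expect_true(all(is.na(got2$cell_type)))

  # differing component counts are refused
  df3 <- as.data.frame(matrix(rnorm(16), 4, 4))
  utils::write.csv(df3, file.path(dir, "c.csv"), row.names = FALSE)
  expect_error(read_samples(file.path(dir, c("a.csv", "c.csv"))),
               "components")
})

test_that("h5ad containers round-trip the PCA slot and categorical obs", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "s1.h5ad")
  pca <- matrix(rnorm(20), 5, 4)
  types <- c("B", "T", "T", "NK", "B")
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "obsm")
  # h5ad is row-major; emulate by storing the transpose
  rhdf5::h5write(t(pca), path, "obsm/X_pca")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5createGroup(path, "obs/cell_type")
  rhdf5::h5write(sort(unique(types)), path, "obs/cell_type/categories")
  rhdf5::h5write(as.integer(factor(types, levels = sort(unique(types)))) - 1L,
                 path, "obs/cell_type/codes")
  rhdf5::h5closeAll()

  got <- read_samples(c(s1 = path), annotation_key = "cell_type")
  expect_equal(got$pca, pca, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(got$cell_type, types)

  # missing PCA slot is a format error
  path2 <- file.path(dir, "bad.h5ad")
  rhdf5::h5createFile(path2)
  rhdf5::h5write(1:3, path2, "something")
  rhdf5::h5closeAll()
  expect_error(read_samples(path2), "X_pca")
})

test_that("annotation key present in only some files is refused", {
  dir <- withr::local_tempdir()
  cells <- make_tiny_collection()
  for (s in c("a", "b")) {
    m <- as.data.frame(cells$pca[cells$sample_id == s, ])
    utils::write.csv(m, file.path(dir, paste0(s, ".csv")), row.names = FALSE)
  }
  writeLines(cells$cell_type[cells$sample_id == "a"],
             file.path(dir, "a_cell_type.txt"))
  expect_error(
    read_samples(file.path(dir, c("a.csv", "b.csv")),
                 annotation_key = "cell_type"),
    "not all"
  )
})

test_that("embedding tables round-trip bit-exactly", {
  emb <- tibble::tibble(
    sample_id = "s", cell_id = paste0("c", 1:7),
    cell_type = c(letters[1:6], NA),
    x = rnorm(7) * 1e3, y = rnorm(7) / 7,
    provenance = "force", seed = 1L
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_embedding(emb, path)
  back <- read_embedding(path)
  expect_identical(back$x, emb$x)
  expect_identical(back$y, emb$y)
  expect_identical(back$provenance, rep("force", 7))
  expect_identical(back$cell_type, emb$cell_type)

  # a single-cell sample writes a single data row
  one <- emb[1, ]
  write_embedding(one, path)
  expect_identical(nrow(read_embedding(path)), 1L)
})
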