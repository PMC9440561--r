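test_that("csv parsing and round trips preserve values, ids and layer tag", {
  m <- expression_matrix(matrix(c(1, 0, 0, 3), 2, 2,
                                dimnames = list(c("g1", "g2"),
                                                c("c1", "c2"))))
  expect_equal(unname(m$values), matrix(c(1, 0, 0, 3), 2, 2))
  expect_identical(m$layer, "counts")

  dir <- withr::local_tempdir()
  p_csv <- file.path(dir, "m.csv")
  write_matrix(m, p_csv, "csv")
  back <- read_matrix(p_csv, "csv")
  expect_identical(back$gene_ids, m$gene_ids)
  expect_identical(back$cell_ids, m$cell_ids)
  expect_lt(max(abs(back$values - m$values)), 1e-12)

  big <- toy_counts(10, 7, seed = 4)
  p_mtx <- file.path(dir, "matrix.mtx")
  write_matrix(big, p_mtx, "mtx")
  back2 <- read_matrix(p_mtx, "mtx")
  expect_identical(back2$gene_ids, big$gene_ids)
  expect_identical(back2$cell_ids, big$cell_ids)
  expect_lt(max(abs(back2$values - big$values)), 1e-12)

  # layer tag survives the metadata sidecar
  lg <- log_transform(normalize_cpm(big))
  p2 <- file.path(dir, "log.tsv")
  write_matrix(lg, p2, "tsv")
  back3 <- read_matrix(p2, "tsv")
  expect_identical(back3$layer, "log")
  expect_equal(back3$theta, 1)
})

test_that("mtx triplets are 1-based externally, matrix indexing internal", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "1 1 5"), file.path(dir, "matrix.mtx"))
  writeLines(c("gA\tgA", "gB\tgB"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  m <- read_matrix(file.path(dir, "matrix.mtx"), "mtx")
  expect_equal(m$values[1, 1], 5)
  expect_equal(sum(m$values), 5)
})

test_that("malformed inputs are rejected with informative messages", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "1 1 1", "1 1 2"), file.path(dir, "matrix.mtx"))
  expect_error(read_matrix(file.path(dir, "matrix.mtx"), "mtx"),
               "sidecar")
  expect_error(expression_matrix(matrix(1, 2, 2),
                                 gene_ids = c("g", "g"),
                                 cell_ids = c("a", "b")),
               "duplicate gene ids")
  v <- matrix(c(1, -2, 3, 4), 2, 2)
  expect_error(expression_matrix(v, c("gA", "gB"), c("c1", "c2")),
               "gB")
})

test_that("CPM normalization matches the formula and is idempotent", {
  m <- expression_matrix(matrix(c(1, 3), 2, 1))
  n <- normalize_cpm(m)
  expect_equal(unname(n$values[, 1]), c(250000, 750000))
  expect_identical(n$layer, "cpm")

  big <- toy_counts(8, 6, seed = 2)
  n1 <- normalize_cpm(big)
  expect_equal(unname(colSums(n1$values)), rep(1e6, 6), tolerance = 1e-9)
  # idempotence
  n2 <- normalize_cpm(n1)
  expect_equal(n2$values, n1$values, tolerance = 1e-12)
  # columnwise: permuting cells commutes with normalization
  perm <- c(3, 1, 2, 6, 5, 4)
  mp <- expression_matrix(big$values[, perm], big$gene_ids,
                          big$cell_ids[perm])
  expect_equal(unname(normalize_cpm(mp)$values),
               unname(n1$values[, perm]))

  zero <- expression_matrix(matrix(c(1, 2, 0, 0), 2, 2,
                                   dimnames = list(NULL, c("ok", "empty"))))
  expect_error(normalize_cpm(zero), "empty")
})

test_that("log transform, its inverse, and monotonicity", {
  m <- expression_matrix(matrix(c(0, 250000), 2, 1), layer = "cpm")
  lg <- log_transform(m)
  expect_equal(lg$values[1, 1], 0)
  expect_equal(lg$values[2, 1], log2(250001))
  expect_error(log_transform(m, theta = 0), "theta")

  big <- normalize_cpm(toy_counts(10, 5, seed = 3))
  round_trip <- inverse_transform(log_transform(big))
  expect_equal(round_trip$values, big$values, tolerance = 1e-9)
  # strict monotonicity preserves within-cell rankings
  lg2 <- log_transform(big)
  for (j in seq_len(5))
    expect_identical(order(lg2$values[, j]), order(big$values[, j]))
  # clip rule: 2^x - theta below zero is clipped
  neg <- expression_matrix(matrix(log2(0.5), 1, 1), layer = "log")
  expect_equal(inverse_transform(neg, theta = 1)$values[1, 1], 0)
})

test_that("filtering matches a brute-force scan and preserves order", {
  m <- toy_counts(12, 9, seed = 5, zero_frac = 0.5)
  expect_equal(filter_matrix(m, 0, 0)$values, m$values)

  one_cell_gene <- expression_matrix(
    rbind(c(5, 0, 0), c(1, 2, 3)), c("rare", "common"), c("a", "b", "c"))
  expect_identical(filter_matrix(one_cell_gene, 2, 0)$gene_ids, "common")

  f <- filter_matrix(m, 3, 4)
  keep_g <- which(rowSums(m$values > 0) >= 3)
  keep_c <- which(colSums(m$values[keep_g, ] > 0) >= 4)
  expect_identical(f$gene_ids, m$gene_ids[keep_g])
  expect_identical(f$cell_ids, m$cell_ids[keep_c])
})
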