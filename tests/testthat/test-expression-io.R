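test_that("dense reader parses, orients, and validates identifiers", {
  p <- write_tsv_lines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4", "g3\t5\t6"))
  em <- read_dense_matrix(p, modality = "bulk")
  expect_s3_class(em, "ExpressionMatrix")
  expect_equal(dim(em), c(3L, 2L))
  expect_equal(em$values["g2", "s2"], 4)
  expect_equal(em$transform_state, "raw")

  # genes in columns -> transposed to genes x samples
  pt <- write_tsv_lines(c("sample\tg1\tg2\tg3", "s1\t1\t3\t5", "s2\t2\t4\t6"))
  emt <- read_dense_matrix(pt, orientation = "genes_in_columns")
  expect_equal(emt$values, em$values)

  dup <- write_tsv_lines(c("gene_id\ts1", "g1\t1", "g1\t2"))
  expect_error(read_dense_matrix(dup), "g1")

  bad <- write_tsv_lines(c("gene_id\ts1", "g1\t1", "g2\tx"))
  expect_error(read_dense_matrix(bad), "non-numeric")
})

test_that("dense write/read round trip is exact", {
  em <- toy_matrix(seed = 42)
  p <- tempfile(fileext = ".tsv")
  write_dense_matrix(em, p)
  back <- read_dense_matrix(p)
  expect_identical(back$values, em$values)
})

test_that("sparse triplet reader fills absent entries with zero and checks sidecars", {
  mtx <- tempfile(fileext = ".mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "1 1 5"), mtx)
  g <- write_tsv_lines(c("g1", "g2"))
  b <- write_tsv_lines(c("c1", "c2"))
  em <- read_sparse_triplet(mtx, g, b)
  expect_equal(em$modality, "single_cell")
  expect_equal(unname(em$values), matrix(c(5, 0, 0, 0), 2))

  # out-of-bounds index rejected
  bad <- tempfile(fileext = ".mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "3 1 5"), bad)
  expect_error(read_sparse_triplet(bad, g, b))

  # sidecar length mismatch rejected
  g3 <- write_tsv_lines(c("g1", "g2", "g3"))
  expect_error(read_sparse_triplet(mtx, g3, b), "sidecar")

  # empty body -> all-zero matrix of the declared shape
  empty <- tempfile(fileext = ".mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general", "2 2 0"), empty)
  em0 <- read_sparse_triplet(empty, g, b)
  expect_true(all(em0$values == 0))
  expect_equal(dim(em0), c(2L, 2L))
})

test_that("sparse triplet write/read round trip preserves values", {
  em <- toy_matrix(seed = 5, modality = "single_cell")
  em$values[1, ] <- 0
  m <- tempfile(fileext = ".mtx"); g <- tempfile(); b <- tempfile()
  write_sparse_triplet(em, m, g, b)
  back <- read_sparse_triplet(m, g, b)
  expect_equal(back$values, em$values)
})

test_that("per-million normalization matches the TPM formula", {
  v <- matrix(c(10, 30, 60), 3, dimnames = list(c("a", "b", "c"), "s1"))
  em <- expression_matrix(v, "bulk")
  cpm <- normalize_per_million(em)
  expect_equal(unname(cpm$values[, 1]), c(1e5, 3e5, 6e5))
  expect_equal(cpm$transform_state, "per_million")

  # TPM with unequal lengths, hand-evaluated
  v2 <- matrix(c(2, 2), 2, dimnames = list(c("a", "b"), "s1"))
  tpm <- normalize_per_million(expression_matrix(v2, "bulk"),
                               gene_lengths = c(a = 1, b = 2))
  expect_equal(unname(tpm$values[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-12)

  # every non-zero column sums to 1e6
  em2 <- toy_matrix(genes = letters[1:5], samples = paste0("s", 1:4), seed = 2)
  out <- normalize_per_million(em2)
  expect_equal(unname(colSums(out$values)), rep(1e6, 4))

  # all-zero column left at zero, with a warning
  v3 <- matrix(c(1, 2, 0, 0), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(z <- normalize_per_million(expression_matrix(v3, "bulk")),
                 "all-zero")
  expect_equal(unname(z$values[, 2]), c(0, 0))

  # not re-appliable
  expect_error(normalize_per_million(cpm), "raw")
  expect_error(normalize_per_million(em, gene_lengths = c(a = 0, b = 1, c = 1)),
               "positive")
})

test_that("log transform follows the pseudocount contract and is one-way", {
  v <- matrix(c(0, 99, 7), 3, dimnames = list(c("a", "b", "c"), "s1"))
  em <- expression_matrix(v, "bulk")
  l10 <- log_transform(em)
  expect_equal(unname(l10$values[, 1]), c(0, 2, log10(8)))
  l2 <- log_transform(em, base = 2)
  expect_equal(l2$values["c", 1], 3)
  expect_error(log_transform(em, pseudocount = 0), "-Inf")
  expect_error(log_transform(l10), "transform_state")
})

test_that("gene-universe alignment intersects, drops silent genes, and preserves order", {
  bulk <- toy_matrix(genes = c("g1", "g2", "g3", "g4"), seed = 1)
  sc <- toy_matrix(genes = c("g2", "g3", "g5"), seed = 2, modality = "single_cell")
  al <- align_gene_universe(bulk, sc)
  expect_equal(al$shared_genes, c("g2", "g3"))
  expect_identical(gene_ids(al$bulk), gene_ids(al$sc))

  # gene all-zero in one modality is dropped even if expressed in the other
  sc2 <- sc
  sc2$values["g2", ] <- 0
  al2 <- align_gene_universe(bulk, sc2)
  expect_equal(al2$shared_genes, "g3")

  # identical matrices pass through unchanged
  al3 <- align_gene_universe(bulk, bulk)
  expect_equal(al3$bulk$values, bulk$values)

  sc3 <- toy_matrix(genes = c("x1", "x2"), seed = 3, modality = "single_cell")
  expect_error(align_gene_universe(bulk, sc3), "share no gene")
})

test_that("construction rejects invalid matrices", {
  v <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s", "s")))
  expect_error(expression_matrix(v, "bulk"), "duplicated sample")
  v2 <- matrix(c(1, -1, 2, 3), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(v2, "bulk"), "non-negative")
})
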