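test_that("cell and gene filters apply thresholds, cells first", {
  # 5 cells; cell 1 expresses only 4 genes
  counts <- matrix(1, 5, 12)
  counts[1, 5:12] <- 0
  x <- sc_data(counts, batch = rep("B1", 5))
  f <- filter_cells_genes(x, min_genes = 10, min_cells = 1)
  expect_equal(nrow(f$values), 4)
  expect_false("cell1" %in% rownames(f$values))

  # identity case: all cells >= 10 genes, all genes >= 3 cells
  x2 <- sc_data(matrix(1, 6, 15), batch = rep("B1", 6))
  f2 <- filter_cells_genes(x2)
  expect_equal(dim(f2$values), c(6, 15))

  # gene present in exactly 2 cells is dropped at min_cells = 3
  counts3 <- matrix(1, 5, 12)
  counts3[3:5, 12] <- 0
  x3 <- sc_data(counts3, batch = rep("B1", 5))
  f3 <- filter_cells_genes(x3, min_genes = 1, min_cells = 3)
  expect_false("gene12" %in% colnames(f3$values))

  # cells-first order: gene filtering may drop a retained cell below
  # min_genes, and the cell filter is not re-applied
  counts4 <- rbind(
    c(1, 1, 0, 0, 0),  # cell A: 2 genes, one of which is cell-A-only
    c(1, 0, 1, 1, 1),
    c(1, 0, 1, 1, 1),
    c(1, 0, 1, 1, 1)
  )
  x4 <- sc_data(counts4, batch = rep("B1", 4))
  f4 <- filter_cells_genes(x4, min_genes = 2, min_cells = 3)
  expect_true("cell1" %in% rownames(f4$values))      # passed the cell filter
  expect_false("gene2" %in% colnames(f4$values))     # dropped by gene filter
  expect_lt(sum(f4$values[1, ] > 0), 2)              # now below min_genes

  expect_error(filter_cells_genes(x, min_genes = 1000), "empty-after-filter")
})

test_that("library-size normalization matches the forced arithmetic", {
  x <- sc_data(matrix(c(1, 1, 2), 1, 3), batch = "B1")
  norm <- normalize_log(x)
  expect_equal(expm1(norm$values[1, ]), c(2500, 2500, 5000),
               ignore_attr = TRUE)

  # pre-log row sums all equal target_sum
  y <- make_tiny_counts(seed = 2)
  ny <- normalize_log(y)
  expect_equal(rowSums(expm1(ny$values)), rep(1e4, nrow(y$values)),
               ignore_attr = TRUE, tolerance = 1e-8)

  # all-equal counts -> target_sum / g everywhere
  xe <- sc_data(matrix(4, 2, 8), batch = c("B1", "B1"))
  ne <- normalize_log(xe)
  expect_equal(unique(as.vector(round(expm1(ne$values), 8))), 1e4 / 8)

  # zero-total cell fails, naming the cell
  bad <- sc_data(rbind(c(1, 2), c(0, 0)), batch = c("B1", "B1"))
  expect_error(normalize_log(bad), "cell2")
})

test_that("round trip recovers column-proportional counts", {
  y <- make_tiny_counts(seed = 5)
  ny <- normalize_log(y)
  rec <- expm1(ny$values) * rowSums(y$values) / 1e4
  expect_equal(rec, y$values, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("HVG selection ranks by dispersion and is deterministic", {
  y <- normalize_log(make_tiny_counts(n = 60, p = 50, seed = 3))
  p <- ncol(y$values)
  all_genes <- select_hvgs(y, n_hvg = p)
  expect_setequal(colnames(all_genes$values), colnames(y$values))

  # a zero-variance gene is never selected when n_hvg < p
  yc <- y
  yc$values[, 7] <- 1.5
  sel <- select_hvgs(yc, n_hvg = 20)
  expect_false(colnames(y$values)[7] %in% colnames(sel$values))

  s1 <- select_hvgs(y, n_hvg = 25)
  s2 <- select_hvgs(y, n_hvg = 25)
  expect_identical(colnames(s1$values), colnames(s2$values))

  expect_error(select_hvgs(y, n_hvg = p + 1), "n_hvg")
})

test_that("per-batch scaling centers, zeroes constants and truncates", {
  y <- normalize_log(make_tiny_counts(n = 40, p = 30, seed = 4))
  sc <- scale_per_batch(y, max_value = 1e6)  # no truncation interference
  for (b in levels(y$batch)) {
    mu <- colMeans(sc$values[sc$batch == b, , drop = FALSE])
    expect_lt(max(abs(mu)), 1e-6)
    sdv <- apply(sc$values[sc$batch == b, , drop = FALSE], 2, sd)
    expect_true(all(abs(sdv[sdv > 0] - 1) < 1e-6))
  }

  # gene constant within one batch becomes 0 there
  yc <- y
  yc$values[yc$batch == "B1", 3] <- 2
  scc <- scale_per_batch(yc)
  expect_true(all(scc$values[scc$batch == "B1", 3] == 0))

  # truncation clips extreme z-scores
  yz <- y
  yz$values[1, 1] <- 1e3
  expect_equal(max(scale_per_batch(yz, max_value = 2)$values), 2)

  # single-cell batch warns and scales by 1
  ys <- sc_data(matrix(runif(20), 4, 5), batch = c("B1", "B1", "B1", "B2"),
                normalized = TRUE)
  expect_warning(scale_per_batch(ys), "single cell")
})

test_that("PCA preserves rank-2 geometry and total variance", {
  set.seed(9)
  basis <- matrix(rnorm(2 * 12), 2, 12)
  scores_true <- matrix(rnorm(40 * 2), 40, 2)
  m <- scores_true %*% basis
  pc <- pca_embed(m, n_pca = 2)
  # distances between rows are preserved exactly by a rank-2 embedding
  expect_equal(as.matrix(dist(pc)), as.matrix(dist(m)),
               ignore_attr = TRUE, tolerance = 1e-6)

  y <- scale_per_batch(normalize_log(make_tiny_counts(n = 50, p = 30, seed = 6)))
  pc2 <- pca_embed(y, n_pca = 10)
  expect_lte(sum(apply(pc2, 2, var)), sum(apply(y$values, 2, var)) + 1e-8)

  expect_identical(pca_embed(y, n_pca = 10, seed = 1),
                   pca_embed(y, n_pca = 10, seed = 1))
  expect_error(pca_embed(y, n_pca = 1000), "maximum admissible is 30")
})
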