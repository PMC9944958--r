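test_that("ARI matches the contingency-table definition", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # label-renaming invariance
  expect_equal(ari(c(1, 1, 2, 2, 3), c(7, 7, 5, 5, 2)), 1)

  set.seed(21)
  for (r in 1:20) {
    truth <- sample(1:4, 100, replace = TRUE)
    pred <- sample(1:5, 100, replace = TRUE)
    expect_equal(ari(truth, pred), oracle_ari(truth, pred), tolerance = 1e-9)
    # symmetry
    expect_equal(ari(truth, pred), ari(pred, truth), tolerance = 1e-12)
  }
  # agreement with an established implementation
  if (requireNamespace("mclust", quietly = TRUE)) {
    set.seed(22)
    truth <- sample(1:3, 200, replace = TRUE)
    pred <- sample(1:4, 200, replace = TRUE)
    expect_equal(ari(truth, pred), mclust::adjustedRandIndex(truth, pred),
                 tolerance = 1e-12)
  }
  expect_error(ari(1:3, 1:4), "length")
})

test_that("NMI matches the entropy formula", {
  expect_equal(nmi(c(1, 2, 3, 1), c(1, 2, 3, 1)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(5, 5, 5, 5)), 0)
  set.seed(23)
  for (r in 1:20) {
    truth <- sample(1:4, 100, replace = TRUE)
    pred <- sample(1:5, 100, replace = TRUE)
    expect_equal(nmi(truth, pred), oracle_nmi(truth, pred), tolerance = 1e-9)
    expect_equal(nmi(truth, pred), nmi(pred, truth), tolerance = 1e-12)
  }
})

test_that("silhouette separates tight clusters and is null on noise", {
  set.seed(24)
  emb <- rbind(matrix(rnorm(100, 0, 0.2), 50, 2),
               matrix(rnorm(100, 30, 0.2), 50, 2))
  lab <- rep(1:2, each = 50)
  s <- asw(emb, lab)
  expect_gt(s$raw, 0.9)
  expect_equal(s$scaled, (s$raw + 1) / 2)

  # labels random with respect to geometry
  emb_r <- matrix(rnorm(400), 200, 2)
  lab_r <- rep(1:2, 100)
  expect_lt(abs(asw(emb_r, lab_r)$raw), 0.1)

  # singleton label warns and contributes 0
  emb1 <- rbind(c(0, 0), c(0.1, 0), c(40, 40))
  expect_warning(s1 <- asw(emb1, c(1, 1, 2)), "singleton")

  # isometry invariance
  rot <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  expect_equal(asw(emb %*% rot + 5, lab)$raw, s$raw, tolerance = 1e-10)
})

test_that("iLISI hits its mixing and separation limits", {
  # two batches perfectly interleaved on a circle
  n <- 120
  th <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  circ <- cbind(cos(th), sin(th)) * 50
  alt <- rep(c("A", "B"), n / 2)
  expect_gt(ilisi(circ, alt, perplexity = 10), 1.8)

  # two far-separated batches
  emb_sep <- rbind(matrix(rnorm(200, 0, 0.5), 100, 2),
                   matrix(rnorm(200, 500, 0.5), 100, 2))
  b_sep <- rep(c("A", "B"), each = 100)
  expect_lt(ilisi(emb_sep, b_sep, perplexity = 10), 1.1)

  # random mixing of 3 equal batches
  set.seed(25)
  emb_mix <- matrix(rnorm(600), 300, 2)
  b_mix <- rep(c("A", "B", "C"), 100)
  v <- ilisi(emb_mix, b_mix, perplexity = 30)
  expect_gt(v, 2.5)
  expect_lte(v, 3.0 + 1e-9)

  # single batch is 1 by definition
  expect_equal(ilisi(emb_mix, rep("A", 300)), 1.0)
  expect_error(ilisi(emb_mix[1:10, ], b_mix[1:10], perplexity = 30),
               "perplexity")
})

test_that("BatchKL vanishes under exact local-global proportion match", {
  # alternating circle: every 4-neighbourhood holds 2 cells of each batch
  n <- 80
  th <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  circ <- cbind(cos(th), sin(th)) * 100
  alt <- rep(c("A", "B"), n / 2)
  expect_equal(batchkl(circ, alt, k_neighbors = 4, seed = 1), 0)

  # fully separated batches reach at least the global entropy (equal sizes)
  emb_sep <- rbind(matrix(rnorm(120, 0, 0.5), 60, 2),
                   matrix(rnorm(120, 500, 0.5), 60, 2))
  b_sep <- rep(c("A", "B"), each = 60)
  expect_gte(batchkl(emb_sep, b_sep, k_neighbors = 10, seed = 1),
             log(2) - 1e-9)

  # seed determinism and isometry invariance
  set.seed(26)
  emb <- matrix(rnorm(300), 150, 2)
  b <- rep(c("A", "B", "C"), 50)
  v1 <- batchkl(emb, b, seed = 9)
  expect_identical(v1, batchkl(emb, b, seed = 9))
  rot <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  expect_equal(batchkl(emb %*% rot + 3, b, seed = 9), v1, tolerance = 1e-10)
  expect_error(batchkl(emb, b, k_neighbors = 150), "k_neighbors")
})

test_that("the metrics report assembles all six quantities", {
  set.seed(27)
  emb <- rbind(matrix(rnorm(120, 0, 0.5), 60, 2),
               matrix(rnorm(120, 20, 0.5), 60, 2))
  truth <- rep(1:2, each = 60)
  pred <- truth
  batch <- rep(c("A", "B"), 60)
  rep1 <- evaluate_integration(emb, pred, batch, truth = truth, perplexity = 10)
  expect_s3_class(rep1, "tbl_df")
  expect_equal(nrow(rep1), 1)
  expect_named(rep1, c("ari", "nmi", "asw_celltype", "asw_batch",
                       "ilisi", "batchkl"))
  expect_equal(rep1$ari, 1)
  expect_equal(rep1$nmi, 1)
  # without truth the clustering metrics are NA, mixing metrics remain
  rep2 <- evaluate_integration(emb, pred, batch, perplexity = 10)
  expect_true(is.na(rep2$ari) && is.na(rep2$nmi))
  expect_false(is.na(rep2$ilisi))
})
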