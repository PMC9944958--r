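test_that("pair counting fills A with ordered-pair counts, zero diagonal", {
  pairs <- tibble::tibble(i = c(1, 2), j = c(2, 1), kind = "intra")
  cs <- count_pairs(pairs, labels = c(1, 2))
  expect_equal(cs$A, rbind(c(0, 2), c(2, 0)))
  expect_equal(cs$sizes, c(1, 1))

  # all pairs within one cluster -> zero matrix
  cs2 <- count_pairs(pairs, labels = c(1, 1, 2))
  expect_true(all(cs2$A == 0))

  # random instance vs an independent nested-loop recount
  set.seed(8)
  n <- 100
  lab <- sample(1:6, n, replace = TRUE)
  src <- sample(n, 300, replace = TRUE)
  dst <- sample(n, 300, replace = TRUE)
  keep <- src != dst
  pr <- tibble::tibble(i = c(src[keep], dst[keep]),
                       j = c(dst[keep], src[keep]), kind = "intra")
  pr <- pr[!duplicated(pr[, 1:2]), ]
  cs3 <- count_pairs(pr, lab)
  Aref <- matrix(0, 6, 6)
  for (r in seq_len(nrow(pr))) {
    ci <- lab[pr$i[r]]; cj <- lab[pr$j[r]]
    if (ci != cj) {
      Aref[ci, cj] <- Aref[ci, cj] + 1
      Aref[cj, ci] <- Aref[cj, ci] + 1
    }
  }
  expect_equal(cs3$A, Aref)
  expect_true(isSymmetric(cs3$A))
})

test_that("similarity normalizes by the smaller cluster size", {
  cs <- structure(list(A = rbind(c(0, 4), c(4, 0)), sizes = c(2, 4), S = NULL),
                  class = "cluster_similarity")
  s <- similarity_from_counts(cs)
  expect_equal(s$S[1, 2], 2.0)

  csz <- structure(list(A = matrix(0, 3, 3), sizes = c(1, 2, 3), S = NULL),
                   class = "cluster_similarity")
  expect_true(all(similarity_from_counts(csz)$S == 0))

  # homogeneity: doubling both sizes halves s when counts are fixed
  cs2 <- structure(list(A = rbind(c(0, 4), c(4, 0)), sizes = c(4, 8), S = NULL),
                   class = "cluster_similarity")
  expect_equal(similarity_from_counts(cs2)$S[1, 2], 1.0)

  bad <- structure(list(A = matrix(0, 2, 2), sizes = c(0, 3), S = NULL),
                   class = "cluster_similarity")
  expect_error(similarity_from_counts(bad), "zero-size")
})

test_that("eigengap candidates include clean block counts", {
  # two strongly connected blocks, nothing between
  S <- matrix(0, 6, 6)
  S[1:3, 1:3] <- 5; S[4:6, 4:6] <- 5
  diag(S) <- 0
  expect_true(2 %in% infer_n_clusters(S))

  # all-zero similarity: no evidence to merge
  expect_warning(k0 <- infer_n_clusters(matrix(0, 4, 4)), "all zero")
  expect_equal(k0, 4)

  # three blocks with sub-1% off-block noise
  set.seed(11)
  S3 <- matrix(runif(81) * 0.01, 9, 9)
  for (b in list(1:3, 4:6, 7:9)) S3[b, b] <- 1 + runif(9) * 0.1
  S3 <- (S3 + t(S3)) / 2; diag(S3) <- 0
  expect_true(3 %in% infer_n_clusters(S3))
})

test_that("greedy merging matches examples and the independent oracle", {
  # target_K = C: nothing happens
  cs <- structure(list(A = rbind(c(0, 4), c(4, 0)), sizes = c(2, 2), S = NULL),
                  class = "cluster_similarity")
  plan0 <- merge_clusters(cs, 2)
  expect_equal(nrow(plan0$events), 0)
  expect_equal(plan0$label_map, c(1, 2))

  # unique maximum merges (1, 2) only
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 10; A[1, 3] <- A[3, 1] <- 0.2
  cs1 <- structure(list(A = A, sizes = c(2, 2, 2), S = NULL),
                   class = "cluster_similarity")
  plan1 <- merge_clusters(cs1, 2)
  expect_equal(nrow(plan1$events), 1)
  expect_equal(c(plan1$events$u, plan1$events$v), c(1, 2))
  expect_equal(plan1$label_map, c(1, 1, 2))

  # nested structure: tight pairs merge before the weak cross link
  A2 <- matrix(0, 4, 4)
  A2[1, 2] <- A2[2, 1] <- 50
  A2[3, 4] <- A2[4, 3] <- 40
  A2[2, 3] <- A2[3, 2] <- 5
  cs2 <- structure(list(A = A2, sizes = rep(10, 4), S = NULL),
                   class = "cluster_similarity")
  plan2 <- merge_clusters(cs2, 2)
  expect_equal(plan2$events$u, c(1, 3))
  expect_equal(plan2$events$v, c(2, 4))
  expect_equal(plan2$components, list(c(1, 2), c(3, 4)))

  # random instances agree with the from-scratch oracle, full event order
  for (s in 1:10) {
    set.seed(s)
    C <- sample(4:9, 1)
    A <- matrix(0, C, C)
    A[upper.tri(A)] <- rpois(C * (C - 1) / 2, 4)
    A <- A + t(A)
    sizes <- sample(2:30, C, replace = TRUE)
    cs <- structure(list(A = A, sizes = sizes, S = NULL),
                    class = "cluster_similarity")
    tk <- sample(seq_len(C - 1), 1)
    plan <- suppressWarnings(merge_clusters(cs, tk))
    orc <- oracle_merge(A, sizes, tk)
    if (is.null(orc$events)) {
      expect_equal(nrow(plan$events), 0)
    } else {
      expect_equal(as.matrix(plan$events),
                   unname(orc$events), ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("merging stops early when similarities are exhausted", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 3
  cs <- structure(list(A = A, sizes = c(2, 2, 2), S = NULL),
                  class = "cluster_similarity")
  expect_warning(plan <- merge_clusters(cs, 1), "achieved K = 2")
  expect_equal(plan$K, 2)
})

test_that("label reassignment follows connected components", {
  cs <- structure(list(A = rbind(c(0, 4, 0), c(4, 0, 0), c(0, 0, 0)),
                       sizes = c(1, 2, 1), S = NULL),
                  class = "cluster_similarity")
  plan <- merge_clusters(cs, 2)
  lab <- reassign_labels(plan, c(1, 2, 2, 3))
  expect_equal(lab, c(1, 1, 1, 2))

  # empty plan: labels unchanged up to renumbering
  plan0 <- merge_clusters(cs, 3)
  expect_equal(reassign_labels(plan0, c(3, 1, 2)), c(3, 1, 2))

  # random plans on 50 clusters vs an independent union-find
  for (s in 1:5) {
    set.seed(s)
    C <- 50
    edges <- cbind(sample(C, 30, replace = TRUE), sample(C, 30, replace = TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, C - igraph::vcount(g))
    ref_comp <- igraph::components(g)$membership
    plan <- structure(list(events = tibble::tibble(u = edges[, 1], v = edges[, 2],
                                                   similarity = 1),
                           edges = edges,
                           components = NULL, K = NA, label_map = NULL),
                      class = "merge_plan")
    # rebuild the label map the way merge_clusters does
    comp_id <- dmlalign:::.components_from_edges(C, edges)
    plan$label_map <- match(comp_id, sort(unique(comp_id)))
    cells <- sample(C, 200, replace = TRUE)
    expect_equal(ari(reassign_labels(plan, cells), ref_comp[cells]), 1)
  }
})

test_that("similarity recomputed from exported counts matches exactly", {
  for (s in 1:5) {
    set.seed(100 + s)
    emb <- matrix(rnorm(80 * 5), 80, 5)
    b <- rep(c("A", "B"), each = 40)
    lab <- sample(1:5, 80, replace = TRUE)
    pr <- union_pairs(knn_pairs_intra(emb, b, 3), mnn_pairs_inter(emb, b, 4))
    cs <- similarity_from_counts(count_pairs(pr, lab))
    C <- length(cs$sizes)
    mn <- pmin(matrix(cs$sizes, C, C), matrix(cs$sizes, C, C, byrow = TRUE))
    Sref <- cs$A / mn; diag(Sref) <- 0
    expect_identical(cs$S, Sref)
  }
})
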