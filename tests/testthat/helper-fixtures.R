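# Small fixtures shared across test files; everything is generated in code.

# well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per = 200, k = 4, d = 10, sep = 20, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d) * sep
  emb <- do.call(rbind, lapply(seq_len(k), function(b) {
    sweep(matrix(rnorm(n_per * d, sd = sd), n_per, d), 2, centers[b, ], "+")
  }))
  list(emb = emb, blob = rep(seq_len(k), each = n_per))
}

# tiny raw-count sc_data built by hand
make_tiny_counts <- function(n = 30, p = 40, n_batches = 2, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n * p, lambda = 3) + rbinom(n * p, 1, 0.2) * 5, n, p)
  sc_data(counts, batch = rep(paste0("B", seq_len(n_batches)), length.out = n))
}

# independent loop-based contingency evaluation of the adjusted Rand index
oracle_ari <- function(truth, pred) {
  truth <- as.integer(as.factor(truth)); pred <- as.integer(as.factor(pred))
  n <- length(truth)
  nij <- matrix(0, max(truth), max(pred))
  for (c1 in seq_len(max(truth))) for (c2 in seq_len(max(pred)))
    nij[c1, c2] <- sum(truth == c1 & pred == c2)
  ch2 <- function(x) ifelse(x >= 2, choose(x, 2), 0)
  sij <- sum(ch2(nij)); sa <- sum(ch2(rowSums(nij))); sb <- sum(ch2(colSums(nij)))
  ex <- sa * sb / ch2(n)
  den <- (sa + sb) / 2 - ex
  if (den == 0) return(1)
  (sij - ex) / den
}

# independent entropy-formula evaluation of NMI (arithmetic-mean normalization)
oracle_nmi <- function(truth, pred) {
  truth <- as.integer(as.factor(truth)); pred <- as.integer(as.factor(pred))
  n <- length(truth)
  mi <- 0
  for (c1 in unique(truth)) for (c2 in unique(pred)) {
    nij <- sum(truth == c1 & pred == c2)
    if (nij > 0) {
      ai <- sum(truth == c1); bj <- sum(pred == c2)
      mi <- mi + nij / n * log(n * nij / (ai * bj))
    }
  }
  h <- function(lab) {
    cnt <- table(lab)
    sum(cnt / n * log(n / cnt))
  }
  ha <- h(truth); hb <- h(pred)
  if (ha + hb == 0) return(1)
  2 * mi / (ha + hb)
}

# brute-force cosine k-nearest-neighbour sets (independent of the package path)
oracle_cosine_knn <- function(emb, query_idx, pool_idx, k) {
  cosd <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  lapply(query_idx, function(i) {
    d <- vapply(pool_idx, function(j) cosd(emb[i, ], emb[j, ]), numeric(1))
    pool_idx[order(d, pool_idx)][seq_len(k)]
  })
}

# canonical sorted representation of a pair set for equality checks
pair_key <- function(pairs) sort(paste(pairs$i, pairs$j))

# independent greedy merge oracle: recompute group similarities from the raw
# count matrix at every step (no incremental update)
oracle_merge <- function(A, sizes, target_K) {
  C <- length(sizes)
  groups <- as.list(seq_len(C))
  events <- NULL
  while (length(groups) > target_K) {
    G <- length(groups)
    best <- -Inf; bu <- bv <- NA; i1 <- i2 <- NA
    for (g1 in seq_len(G - 1)) for (g2 in seq((g1 + 1), G)) {
      a <- sum(A[groups[[g1]], groups[[g2]], drop = FALSE])
      s <- a / min(sum(sizes[groups[[g1]]]), sum(sizes[groups[[g2]]]))
      u <- min(groups[[g1]]); v <- min(groups[[g2]])
      if (s > best + 1e-12 ||
          (abs(s - best) <= 1e-12 && (u < bu || (u == bu && v < bv)))) {
        best <- s; bu <- u; bv <- v; i1 <- g1; i2 <- g2
      }
    }
    if (best <= 0) break
    events <- rbind(events, c(bu, bv, best))
    groups[[i1]] <- c(groups[[i1]], groups[[i2]])
    groups[[i2]] <- NULL
  }
  list(events = events, groups = groups)
}

# exhaustive O(b^3) hard-triplet enumeration
oracle_mine <- function(emb, labels, idx) {
  out <- NULL
  for (a in idx) for (p in idx) for (n in idx) {
    if (a == p || labels[a] != labels[p] || labels[n] == labels[a]) next
    dap <- sqrt(sum((emb[a, ] - emb[p, ])^2))
    dan <- sqrt(sum((emb[a, ] - emb[n, ])^2))
    if (dan < dap) out <- rbind(out, c(a, p, n))
  }
  out
}

# brute-force intra-batch symmetrized-KNN pair set (the "or" rule)
oracle_intra_pairs <- function(emb, batch, k_in) {
  batch <- as.factor(batch)
  out <- NULL
  for (b in levels(batch)) {
    idx <- which(batch == b)
    if (length(idx) < 2) next
    kb <- min(k_in, length(idx) - 1)
    for (i in idx) {
      nn <- oracle_cosine_knn(emb, i, setdiff(idx, i), kb)[[1]]
      for (j in nn) out <- rbind(out, c(i, j), c(j, i))
    }
  }
  unique(out)
}

# brute-force inter-batch mutual-NN pair set (the "and" rule)
oracle_inter_pairs <- function(emb, batch, k_bw) {
  batch <- as.factor(batch)
  lv <- levels(batch)
  out <- NULL
  for (a in seq_len(length(lv) - 1)) for (b in seq(a + 1, length(lv))) {
    ia <- which(batch == lv[a]); ib <- which(batch == lv[b])
    ka <- min(k_bw, length(ib)); kb <- min(k_bw, length(ia))
    knn_ab <- oracle_cosine_knn(emb, ia, ib, ka)
    knn_ba <- oracle_cosine_knn(emb, ib, ia, kb)
    for (xi in seq_along(ia)) for (yj in seq_along(ib)) {
      if (ib[yj] %in% knn_ab[[xi]] && ia[xi] %in% knn_ba[[yj]])
        out <- rbind(out, c(ia[xi], ib[yj]), c(ib[yj], ia[xi]))
    }
  }
  unique(out)
}
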