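#' Adjusted Rand index
#'
#' Chance-adjusted agreement between two partitions, computed from the
#' contingency table of the two labelings. Invariant to label renaming and
#' symmetric in its arguments; 1 for identical partitions, ~0 for random
#' ones.
#'
#' @param truth,pred label vectors of equal length (any type coercible to
#'   factor).
#' @return ARI in `[-1, 1]` (in `[0, 1]` up to floating error for
#'   non-adversarial partitions).
#' @export
ari <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  n <- length(truth)
  stopifnot(n >= 2)
  tab <- table(truth, pred)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

#' Normalized mutual information
#'
#' Mutual information between two labelings normalized by the arithmetic
#' mean of their entropies: `2 I(U, V) / (H(U) + H(V))`. 1 for identical
#' partitions; 0 when one labeling is constant (no information).
#'
#' @inheritParams ari
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  n <- length(truth)
  stopifnot(n >= 2)
  tab <- table(truth, pred)
  pij <- tab / n
  pa <- rowSums(pij); pb <- colSums(pij)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)  # both partitions trivial and identical
  outer_ab <- outer(pa, pb)
  nzero <- pij > 0
  mi <- sum(pij[nzero] * log(pij[nzero] / outer_ab[nzero]))
  2 * mi / (ha + hb)
}

#' Average silhouette width
#'
#' Mean over cells of `(b_i - a_i) / max(a_i, b_i)` where `a_i` is the
#' mean distance to same-label cells and `b_i` the lowest mean distance to
#' any other label's cells, Euclidean in the evaluation embedding.
#' Computed against cell-type labels it measures cluster purity (higher
#' better); against batch labels it measures batch separation (lower
#' better, i.e. better mixing). Cells in singleton labels contribute 0.
#' The raw value lies in `[-1, 1]`; the rescaled value `(raw + 1) / 2`
#' lies in `[0, 1]` and is the one used where a `[0, 1]` quantity is
#' expected.
#'
#' @param emb cells x d embedding.
#' @param labels per-cell labels (>= 2 distinct).
#' @return list with elements `raw` and `scaled`.
#' @export
asw <- function(emb, labels) {
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) < 2) stop("need at least two distinct labels")
  if (any(tabulate(labels) == 1))
    warning("singleton label(s): affected cells contribute silhouette 0")
  sil <- cluster::silhouette(labels, stats::dist(as.matrix(emb)))
  raw <- mean(sil[, "sil_width"])
  list(raw = raw, scaled = (raw + 1) / 2)
}

#' Integration local inverse Simpson's index (iLISI)
#'
#' For every cell, batch proportions are computed from Gaussian-kernel
#' weights over its nearest neighbours, with the kernel bandwidth
#' calibrated so the weight entropy matches `log(perplexity)`; the
#' per-cell score is the inverse Simpson index `1 / sum_b p_b^2` and the
#' mean over cells is returned. Perfect mixing of M batches gives a score
#' near M; complete separation gives 1.
#'
#' @param emb cells x d embedding.
#' @param batch per-cell batch labels.
#' @param perplexity neighbourhood size parameter (default 30; must be
#'   smaller than the cell count).
#' @return mean iLISI in `[1, M]`.
#' @export
ilisi <- function(emb, batch, perplexity = 30) {
  batch <- droplevels(as.factor(batch))
  M <- nlevels(batch)
  if (M == 1) return(1.0)
  emb <- as.matrix(emb)
  n <- nrow(emb)
  if (perplexity >= n) stop("perplexity must be smaller than the cell count")
  nn <- min(3 * ceiling(perplexity), n - 1)
  D <- .dist_euclidean(emb)
  diag(D) <- Inf
  target <- log(perplexity)
  bcode <- as.integer(batch)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])[seq_len(nn)]
    d2 <- D[i, ord]^2
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-beta * d2)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      h <- log(sw) + beta * sum(d2 * w) / sw
      if (abs(h - target) < 1e-5) break
      if (h > target) {  # entropy too high -> narrow the kernel
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    w <- exp(-beta * d2)
    pr <- w / sum(w)
    pb <- vapply(seq_len(M), function(b) sum(pr[bcode[ord] == b]), numeric(1))
    scores[i] <- 1 / sum(pb^2)
  }
  mean(scores)
}

#' KL divergence of batch mixing (BatchKL)
#'
#' Mean over sampled cells of the Kullback-Leibler divergence between the
#' batch proportions among a cell's k nearest neighbours and the global
#' batch proportions (natural log), averaged over bootstrap replicates.
#' 0 under perfect mixing; large when batches separate.
#'
#' @param emb cells x d embedding.
#' @param batch per-cell batch labels.
#' @param n_boot bootstrap replicates (default 100).
#' @param n_cells cells sampled per replicate (default 100).
#' @param k_neighbors neighbourhood size; default `min(100, floor(n/10))`.
#' @param seed RNG seed for the subsampling.
#' @return mean KL divergence (nats).
#' @export
batchkl <- function(emb, batch, n_boot = 100, n_cells = 100,
                    k_neighbors = NULL, seed = 0) {
  batch <- droplevels(as.factor(batch))
  emb <- as.matrix(emb)
  n <- nrow(emb)
  if (is.null(k_neighbors)) k_neighbors <- max(1, min(100, floor(n / 10)))
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the cell count")
  g <- as.numeric(table(batch)) / n
  M <- nlevels(batch)
  bcode <- as.integer(batch)
  D <- .dist_euclidean(emb)
  diag(D) <- Inf
  # neighbour batch counts are seed-independent; precompute once
  local_q <- matrix(0, n, M)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])[seq_len(k_neighbors)]
    local_q[i, ] <- tabulate(bcode[ord], M) / k_neighbors
  }
  kl_cell <- vapply(seq_len(n), function(i) {
    q <- local_q[i, ]
    nz <- q > 0
    sum(q[nz] * log(q[nz] / g[nz]))
  }, numeric(1))
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(n_boot), function(r) {
    mean(kl_cell[sample.int(n, min(n_cells, n), replace = TRUE)])
  }, numeric(1))
  mean(reps)
}

#' Compute the full integration metrics report
#'
#' One-row tibble with the six benchmark metrics: clustering agreement
#' (ARI, NMI of predicted vs truth labels), cell-type silhouette (purity,
#' higher better), batch silhouette (mixing, lower better), iLISI (near
#' the batch count under good mixing) and BatchKL (near 0 under good
#' mixing). Silhouettes are reported rescaled to `[0, 1]`.
#'
#' @param emb evaluation embedding (cells x d).
#' @param pred predicted cluster labels.
#' @param batch per-cell batch labels.
#' @param truth optional ground-truth cell types; ARI/NMI/ASW_celltype are
#'   `NA` without it.
#' @param perplexity iLISI perplexity.
#' @param seed seed for the BatchKL subsampling.
#' @param ... passed to [batchkl()].
#' @return one-row tibble with columns `ari`, `nmi`, `asw_celltype`,
#'   `asw_batch`, `ilisi`, `batchkl`.
#' @export
evaluate_integration <- function(emb, pred, batch, truth = NULL,
                                 perplexity = 30, seed = 0, ...) {
  has_truth <- !is.null(truth)
  tibble::tibble(
    ari = if (has_truth) ari(truth, pred) else NA_real_,
    nmi = if (has_truth) nmi(truth, pred) else NA_real_,
    asw_celltype = if (has_truth) asw(emb, truth)$scaled else NA_real_,
    asw_batch = asw(emb, batch)$scaled,
    ilisi = ilisi(emb, batch, perplexity = perplexity),
    batchkl = batchkl(emb, batch, seed = seed, ...)
  )
}
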