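#' Nearest-neighbour pair sets
#'
#' Pair sets are tibbles with integer columns `i`, `j` (global cell
#' indices) and a `kind` column (`"intra"` or `"inter"`). Pairs are
#' ordered: `(i, j)` and `(j, i)` are both stored (symmetric closure),
#' mirroring the convention that the two orientations count as distinct
#' pairs. Both searches use cosine distance on the embedding and are
#' computed exactly; ties in the distance ranking are broken by the lower
#' cell index.
#'
#' @name nn_pairs
NULL

# rows scaled to unit L2 norm; zero rows are an error (cosine undefined)
.cosine_normalize <- function(emb) {
  emb <- as.matrix(emb)
  nrm <- sqrt(rowSums(emb^2))
  if (any(nrm == 0)) {
    bad <- which(nrm == 0)[1]
    id <- rownames(emb)[bad]
    stop(sprintf("cosine distance undefined for all-zero embedding row %s",
                 if (is.null(id)) bad else sprintf("'%s' (#%d)", id, bad)))
  }
  emb / nrm
}

# index matrix of the k nearest columns for every row of a cosine
# similarity problem: rows of A against rows of B (self handled by caller)
.top_k <- function(dmat, k) {
  res <- apply(dmat, 1, function(r) order(r)[seq_len(k)])
  if (k == 1) matrix(res, ncol = 1) else t(res)
}

#' Intra-batch KNN pairs
#'
#' Within each batch, cells `i` and `j` form a pair iff at least one of
#' them is among the other's `k_in` nearest neighbours under cosine
#' distance (an "or" condition, i.e. the symmetrized KNN graph).
#'
#' @param emb cells x d embedding.
#' @param batch per-cell batch labels.
#' @param k_in neighbours per cell within its batch (default 5); reduced
#'   with a warning in batches with fewer than `k_in + 1` cells.
#' @return tibble of ordered pairs with `kind = "intra"`.
#' @export
knn_pairs_intra <- function(emb, batch, k_in = 5) {
  stopifnot(k_in >= 1)
  batch <- as.factor(batch)
  nrm <- .cosine_normalize(emb)
  out_i <- integer(0); out_j <- integer(0)
  for (b in levels(batch)) {
    idx <- which(batch == b)
    nb <- length(idx)
    if (nb < 2) next
    kb <- k_in
    if (nb < k_in + 1) {
      kb <- nb - 1
      warning(sprintf("batch '%s' has %d cells; k_in reduced to %d", b, nb, kb))
    }
    d <- 1 - tcrossprod(nrm[idx, , drop = FALSE])
    diag(d) <- Inf
    nnidx <- .top_k(d, kb)
    src <- rep(seq_len(nb), kb)
    dst <- as.vector(nnidx)
    ii <- idx[c(src, dst)]
    jj <- idx[c(dst, src)]
    keep <- !duplicated(cbind(ii, jj))
    out_i <- c(out_i, ii[keep]); out_j <- c(out_j, jj[keep])
  }
  tibble::tibble(i = out_i, j = out_j, kind = rep("intra", length(out_i)))
}

#' Inter-batch MNN pairs
#'
#' For every pair of batches, cells `i` (batch a) and `j` (batch b) form a
#' pair iff `j` is among the `k_bw` nearest batch-b cells of `i` AND `i`
#' is among the `k_bw` nearest batch-a cells of `j` (mutual condition),
#' under cosine distance.
#'
#' @inheritParams knn_pairs_intra
#' @param k_bw cross-batch neighbours per cell (default 10).
#' @return tibble of ordered pairs with `kind = "inter"`; empty (with a
#'   warning) when only one batch is present.
#' @export
mnn_pairs_inter <- function(emb, batch, k_bw = 10) {
  stopifnot(k_bw >= 1)
  batch <- as.factor(batch)
  nrm <- .cosine_normalize(emb)
  lv <- levels(batch)
  if (length(lv) < 2) {
    warning("fewer than two batches; no inter-batch pairs")
    return(tibble::tibble(i = integer(0), j = integer(0), kind = character(0)))
  }
  out_i <- integer(0); out_j <- integer(0)
  for (ai in seq_len(length(lv) - 1)) {
    for (bi in seq(ai + 1, length(lv))) {
      ia <- which(batch == lv[ai]); ib <- which(batch == lv[bi])
      ka <- min(k_bw, length(ib)); kb <- min(k_bw, length(ia))
      if (ka < k_bw || kb < k_bw)
        warning(sprintf("k_bw reduced for batch pair (%s, %s): batch sizes %d, %d",
                        lv[ai], lv[bi], length(ia), length(ib)))
      d <- 1 - tcrossprod(nrm[ia, , drop = FALSE], nrm[ib, , drop = FALSE])
      # membership of j in knn_b(i)
      ab <- matrix(FALSE, length(ia), length(ib))
      top_ab <- .top_k(d, ka)
      ab[cbind(rep(seq_along(ia), ka), as.vector(top_ab))] <- TRUE
      # membership of i in knn_a(j)
      ba <- matrix(FALSE, length(ia), length(ib))
      top_ba <- .top_k(t(d), kb)
      ba[cbind(as.vector(top_ba), rep(seq_along(ib), kb))] <- TRUE
      mut <- which(ab & ba, arr.ind = TRUE)
      if (nrow(mut) > 0) {
        gi <- ia[mut[, 1]]; gj <- ib[mut[, 2]]
        out_i <- c(out_i, gi, gj); out_j <- c(out_j, gj, gi)
      }
    }
  }
  tibble::tibble(i = out_i, j = out_j, kind = rep("inter", length(out_i)))
}

#' Union of intra- and inter-batch pair sets
#'
#' @param intra,inter pair tibbles from [knn_pairs_intra()] and
#'   [mnn_pairs_inter()].
#' @return combined pair tibble (duplicates removed); the total pair count
#'   is `nrow()` of the result.
#' @export
union_pairs <- function(intra, inter) {
  all <- rbind(intra, inter)
  all[!duplicated(all[, c("i", "j")]), ]
}
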