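#' Triplet loss
#'
#' `max(d_ap - d_an + margin, 0)` for anchor-positive distance `d_ap` and
#' anchor-negative distance `d_an` (Euclidean distances, so non-negative).
#' Vectorized over its arguments.
#'
#' @param d_ap,d_an non-negative distances.
#' @param margin margin between similar and dissimilar pairs (default 0.2).
#' @return numeric loss value(s).
#' @export
triplet_loss <- function(d_ap, d_an, margin = 0.2) {
  if (any(d_ap < 0) || any(d_an < 0)) stop("distances must be non-negative")
  pmax(d_ap - d_an + margin, 0)
}

#' Classify a triplet as easy, semi-hard or hard
#'
#' Easy: `d_ap + margin < d_an` (loss 0). Hard: `d_an < d_ap` (negative
#' closer to the anchor than the positive). Semi-hard: everything between,
#' including the boundary ties `d_an == d_ap` and `d_an == d_ap + margin`.
#'
#' @inheritParams triplet_loss
#' @return character vector in `c("easy", "semi_hard", "hard")`.
#' @export
classify_triplet <- function(d_ap, d_an, margin = 0.2) {
  if (any(d_ap < 0) || any(d_an < 0)) stop("distances must be non-negative")
  out <- rep("semi_hard", length(d_ap))
  out[d_ap + margin < d_an] <- "easy"
  out[d_an < d_ap] <- "hard"
  out
}

# squared-then-rooted Euclidean distance matrix
.dist_euclidean <- function(E) {
  sq <- rowSums(E^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(E)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  sqrt(d2)
}

#' Mine all hard triplets in a minibatch
#'
#' Enumerates every (anchor, positive, negative) triple within `minibatch`
#' whose negative is strictly closer to the anchor than its positive under
#' the current embedding (the "hard" category).
#'
#' @param emb cells x d embedding matrix.
#' @param labels per-cell integer cluster labels.
#' @param minibatch cell indices forming the minibatch (default: all).
#' @return tibble with columns `anchor`, `positive`, `negative` (global
#'   cell indices); empty (with a warning) when the minibatch holds a
#'   single label.
#' @export
mine_hard_triplets <- function(emb, labels, minibatch = seq_len(nrow(emb))) {
  labels <- as.integer(labels)
  lb <- labels[minibatch]
  empty <- tibble::tibble(anchor = integer(0), positive = integer(0),
                          negative = integer(0))
  if (length(unique(lb)) < 2) {
    warning("minibatch contains a single label; no triplets")
    return(empty)
  }
  D <- .dist_euclidean(emb[minibatch, , drop = FALSE])
  res_a <- integer(0); res_p <- integer(0); res_n <- integer(0)
  for (ai in seq_along(minibatch)) {
    P <- which(lb == lb[ai]); P <- P[P != ai]
    if (length(P) == 0) next
    N <- which(lb != lb[ai])
    dp <- D[ai, P]; dn <- D[ai, N]
    hard <- outer(dp, dn, ">")  # d_an < d_ap
    hits <- which(hard, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      res_a <- c(res_a, rep(ai, nrow(hits)))
      res_p <- c(res_p, P[hits[, 1]])
      res_n <- c(res_n, N[hits[, 2]])
    }
  }
  tibble::tibble(anchor = minibatch[res_a], positive = minibatch[res_p],
                 negative = minibatch[res_n])
}

#' Train the batch-correcting embedding network
#'
#' Learns a nonlinear map from the scaled HVG matrix to a low-dimensional
#' embedding by minimizing the mean triplet loss over all hard triplets
#' mined within each minibatch, supervised by the merged cluster labels.
#' The network is a two-layer perceptron (input -> ReLU hidden ->
#' linear embedding) trained with Adam. Minibatches are label-balanced
#' (cells drawn from several labels per batch) so that hard triplets are
#' mineable; batch identity is never visible to the trainer.
#'
#' @param x scaled [sc_data] or a cells x features numeric matrix.
#' @param labels per-cell merged cluster labels in `1..K`.
#' @param hidden_dim,embed_dim layer widths (defaults 256 and 32).
#' @param margin triplet margin (default 0.2).
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 256).
#' @param lr Adam learning rate (default 1e-3).
#' @param labels_per_batch number of distinct labels sampled per
#'   minibatch (capped at the number of labels; at least 4 where possible).
#' @param seed RNG seed; the full loss trajectory is reproducible.
#' @param verbose print per-epoch loss.
#' @return cells x `embed_dim` embedding matrix of class `dml_embedding`
#'   with attributes `train_log` (tibble: epoch, mean_loss,
#'   n_hard_triplets), `net` (weights) and `space = "learned"`.
#' @export
train_embedding <- function(x, labels, hidden_dim = 256, embed_dim = 32,
                            margin = 0.2, epochs = 50, batch_size = 256,
                            lr = 1e-3, labels_per_batch = 8, seed = 0,
                            verbose = FALSE) {
  X <- if (inherits(x, "sc_data")) x$values else as.matrix(x)
  labels <- as.integer(labels)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(labels) == n)
  tab <- tabulate(labels)
  if (any(tab == 1))
    warning("labels with a single cell never serve as anchors")
  K <- max(labels)
  lpb <- max(4, min(labels_per_batch, K))
  lpb <- min(lpb, K)

  set.seed(as.integer(seed))
  net <- list(
    W1 = matrix(stats::rnorm(p * hidden_dim, 0, sqrt(2 / p)), p, hidden_dim),
    b1 = numeric(hidden_dim),
    W2 = matrix(stats::rnorm(hidden_dim * embed_dim, 0, sqrt(2 / hidden_dim)),
                hidden_dim, embed_dim),
    b2 = numeric(embed_dim)
  )
  adam <- list(m = lapply(net, function(w) w * 0),
               v = lapply(net, function(w) w * 0), t = 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8

  label_pool <- split(seq_len(n), labels)
  steps <- max(1L, ceiling(n / batch_size))
  log_epoch <- integer(epochs); log_loss <- numeric(epochs)
  log_trip <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ep_loss <- 0; ep_trip <- 0; ep_steps <- 0
    for (st in seq_len(steps)) {
      pick_labels <- sample(seq_len(K), lpb)
      quota <- ceiling(batch_size / lpb)
      mb <- unlist(lapply(pick_labels, function(l) {
        pool <- label_pool[[l]]
        pool[sample.int(length(pool), min(quota, length(pool)))]
      }), use.names = FALSE)
      if (length(mb) > batch_size) mb <- mb[seq_len(batch_size)]
      lb <- labels[mb]
      if (length(unique(lb)) < 2) next

      Xb <- X[mb, , drop = FALSE]
      A1 <- sweep(Xb %*% net$W1, 2, net$b1, "+")
      H <- pmax(A1, 0)
      E <- sweep(H %*% net$W2, 2, net$b2, "+")
      D <- .dist_euclidean(E)

      b <- length(mb)
      G <- matrix(0, b, b)
      n_trip <- 0; loss_sum <- 0
      for (ai in seq_len(b)) {
        P <- which(lb == lb[ai]); P <- P[P != ai]
        if (length(P) == 0) next
        N <- which(lb != lb[ai])
        dp <- D[ai, P]; dn <- D[ai, N]
        hard <- outer(dp, dn, ">")
        cp <- rowSums(hard); cn <- colSums(hard)
        tcount <- sum(cp)
        if (tcount == 0) next
        n_trip <- n_trip + tcount
        loss_sum <- loss_sum + sum(dp * cp) - sum(dn * cn) + tcount * margin
        G[ai, P] <- G[ai, P] + cp
        G[ai, N] <- G[ai, N] - cn
      }
      ep_steps <- ep_steps + 1
      if (n_trip == 0) next
      ep_loss <- ep_loss + loss_sum / n_trip
      ep_trip <- ep_trip + n_trip

      G <- G / n_trip
      Msym <- G + t(G)
      Dinv <- ifelse(D > 0, 1 / D, 0)
      Cf <- Msym * Dinv
      dE <- E * rowSums(Cf) - Cf %*% E

      dW2 <- crossprod(H, dE); db2 <- colSums(dE)
      dH <- dE %*% t(net$W2)
      dH[A1 <= 0] <- 0
      dW1 <- crossprod(Xb, dH); db1 <- colSums(dH)
      grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)

      adam$t <- adam$t + 1
      for (nm in names(net)) {
        adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * grads[[nm]]
        adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- adam$m[[nm]] / (1 - beta1^adam$t)
        vhat <- adam$v[[nm]] / (1 - beta2^adam$t)
        net[[nm]] <- net[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    log_epoch[ep] <- ep
    log_loss[ep] <- if (ep_steps > 0) ep_loss / ep_steps else 0
    log_trip[ep] <- ep_trip
    if (verbose)
      message(sprintf("epoch %3d  mean hard-triplet loss %.5f  (%d triplets)",
                      ep, log_loss[ep], as.integer(ep_trip)))
  }

  H <- pmax(sweep(X %*% net$W1, 2, net$b1, "+"), 0)
  E <- sweep(H %*% net$W2, 2, net$b2, "+")
  rownames(E) <- rownames(X)
  colnames(E) <- paste0("DML", seq_len(embed_dim))
  structure(E,
            train_log = tibble::tibble(epoch = log_epoch,
                                       mean_loss = log_loss,
                                       n_hard_triplets = log_trip),
            net = net, space = "learned", class = c("dml_embedding", "matrix"))
}

#' Final cluster labels on the learned embedding
#'
#' `mode = "reassigned"` (default) returns the merged labels unchanged.
#' `mode = "louvain"` re-clusters the learned embedding with the initial
#' clustering machinery at a user resolution; on well-integrated data the
#' two agree, but Louvain may split large clusters.
#'
#' @param emb learned embedding matrix.
#' @param merged per-cell merged labels.
#' @param mode `"reassigned"` or `"louvain"`.
#' @param resolution,n_neighbors,seed passed to [cluster_init()] for
#'   `mode = "louvain"`.
#' @return integer label vector.
#' @export
final_labels <- function(emb, merged, mode = c("reassigned", "louvain"),
                         resolution = 1.0, n_neighbors = 15, seed = 0) {
  mode <- match.arg(mode)
  if (mode == "reassigned") return(as.integer(merged))
  as.integer(cluster_init(unclass(emb), resolution = resolution,
                          n_neighbors = n_neighbors, seed = seed))
}
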