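#' Initial over-clustering on the PCA embedding
#'
#' Builds a shared-nearest-neighbour (SNN) graph (k Euclidean neighbours,
#' Jaccard edge weights, weak edges pruned) and applies Louvain or Leiden
#' modularity optimization at a deliberately high resolution, so that every
#' initial cluster is small enough to be pure (contained in one true cell
#' type). Correctness downstream needs only purity, never that the number
#' of clusters match the number of types.
#'
#' @param emb cells x d numeric embedding (typically from [pca_embed()]).
#' @param resolution modularity resolution; larger gives more clusters
#'   (default 3.0, intentionally over-fine).
#' @param n_neighbors neighbours for the SNN graph.
#' @param method `"louvain"` (default) or `"leiden"`.
#' @param seed RNG seed (community detection uses R's RNG).
#' @param prune minimum Jaccard weight kept as an edge.
#' @return integer vector of cluster labels in `1..C` with attributes
#'   `n_clusters`, `resolution`, `method`.
#' @export
cluster_init <- function(emb, resolution = 3.0, n_neighbors = 15,
                         method = c("louvain", "leiden"), seed = 0,
                         prune = 1 / 15) {
  method <- match.arg(method)
  emb <- as.matrix(emb)
  n <- nrow(emb)
  if (n < n_neighbors + 1)
    stop(sprintf("need at least n_neighbors + 1 = %d cells", n_neighbors + 1))
  stopifnot(resolution > 0)

  nn <- .knn_euclidean(emb, n_neighbors)
  # neighbour sets include the cell itself, Seurat-style
  sets <- cbind(seq_len(n), nn)
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), ncol(sets)), j = as.vector(sets), x = 1,
    dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(adj)
  k1 <- ncol(sets)
  jac <- shared
  jac@x <- jac@x / (2 * k1 - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(as.integer(seed))
  cl <- if (method == "louvain") {
    igraph::cluster_louvain(g, resolution = resolution)
  } else {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 10)
  }
  labels <- as.integer(igraph::membership(cl))
  # compact to 1..C in order of first appearance (stable across runs)
  labels <- match(labels, unique(labels))
  structure(labels, n_clusters = max(labels), resolution = resolution,
            method = method)
}

# exact k nearest neighbours (Euclidean), self excluded, ties broken by
# lower cell index; returns n x k index matrix
.knn_euclidean <- function(emb, k) {
  n <- nrow(emb)
  sq <- rowSums(emb^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(emb)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  res <- apply(d2, 1, function(r) order(r)[seq_len(k)])
  if (k == 1) matrix(res, ncol = 1) else t(res)
}
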