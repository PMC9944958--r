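#' Count NN pairs between clusters
#'
#' Builds the C x C matrix `A` whose entry `a[i, j]` is the number of
#' ordered NN pairs with one end in cluster i and the other in cluster j.
#' Within-cluster pairs are discarded (zero diagonal). Because the pair
#' set stores both orientations, every undirected link is counted twice,
#' symmetrically; this cancels in the merge argmax.
#'
#' @param pairs pair tibble from [union_pairs()] (or either half).
#' @param labels integer cluster labels in `1..C` covering every cell
#'   referenced by `pairs`.
#' @return object of class `cluster_similarity`: list with `A` (counts),
#'   `sizes` (per-cluster cell counts) and `S` (NULL until
#'   [similarity_from_counts()] is applied).
#' @export
count_pairs <- function(pairs, labels) {
  labels <- as.integer(labels)
  C <- max(labels)
  if (nrow(pairs) > 0 && (max(pairs$i) > length(labels) || max(pairs$j) > length(labels)))
    stop("pair indices exceed the label vector")
  li <- factor(labels[pairs$i], levels = seq_len(C))
  lj <- factor(labels[pairs$j], levels = seq_len(C))
  Tm <- unclass(table(li, lj))
  dimnames(Tm) <- NULL
  Tm <- matrix(as.numeric(Tm), C, C)
  # every ordered pair counts towards both a_ij and a_ji, so one
  # undirected link between clusters contributes 2 to each entry
  A <- Tm + t(Tm)
  diag(A) <- 0
  structure(list(A = A, sizes = tabulate(labels, C), S = NULL),
            class = "cluster_similarity")
}

#' Size-normalized cluster similarity
#'
#' Fills `S` with `s[i, j] = a[i, j] / min(m_i, m_j)`, the pair count
#' normalized by the smaller cluster size, so small clusters are not
#' penalized for having fewer possible pairs.
#'
#' @param cs a `cluster_similarity` from [count_pairs()].
#' @return the same object with `S` filled (symmetric, zero diagonal).
#' @export
similarity_from_counts <- function(cs) {
  stopifnot(inherits(cs, "cluster_similarity"))
  if (any(cs$sizes < 1)) stop("zero-size cluster; labels must use every id in 1..C")
  C <- length(cs$sizes)
  mn <- pmin(matrix(cs$sizes, C, C), matrix(cs$sizes, C, C, byrow = TRUE))
  cs$S <- cs$A / mn
  diag(cs$S) <- 0
  cs
}

#' Candidate cluster numbers from the similarity spectrum
#'
#' Sets the diagonal to the largest observed similarity (every cluster is
#' maximally similar to itself), symmetrically normalizes
#' (`W = D^{-1/2} S D^{-1/2}`, `D` = row sums + eps) and proposes every K
#' at which the descending eigenvalue gap `lambda_K - lambda_{K+1}` is
#' unusually large (exceeds mean gap + 2 sd), plus the K of the global
#' maximum gap. With a block-diagonal similarity, each connected block
#' contributes a leading eigenvalue near 1, so the gap falls right after
#' the block count; the self-affinity diagonal makes single-cluster
#' blocks (e.g. a batch-unique cell type with no strong links) count as
#' blocks too, which a zero diagonal would hide.
#'
#' @param cs a `cluster_similarity` with `S` filled, or a plain symmetric
#'   non-negative matrix.
#' @param eps regularizer added to the degree before normalization.
#' @return ascending integer vector of candidate cluster numbers; `C`
#'   itself (with a warning) when the similarity is all zero.
#' @export
infer_n_clusters <- function(cs, eps = 1e-12) {
  S <- if (inherits(cs, "cluster_similarity")) cs$S else as.matrix(cs)
  if (is.null(S)) stop("similarity not filled; call similarity_from_counts() first")
  C <- nrow(S)
  stopifnot(C >= 2)
  S <- (S + t(S)) / 2
  diag(S) <- 0
  if (all(S == 0)) {
    warning("similarity is all zero; no evidence to merge")
    return(C)
  }
  diag(S) <- max(S)
  dinv <- 1 / sqrt(rowSums(S) + eps)
  W <- S * tcrossprod(dinv)
  ev <- sort(eigen(W, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  gaps <- ev[-C] - ev[-1]
  cand <- which.max(gaps)
  if (length(gaps) > 1) {
    thr <- mean(gaps) + 2 * stats::sd(gaps)
    cand <- union(cand, which(gaps > thr))
  }
  sort(unique(as.integer(cand)))
}

#' Greedy hierarchical cluster merging
#'
#' Performs `C - target_K` agglomerative steps. Each step merges the pair
#' of active clusters with the maximum current similarity (ties broken by
#' the lexicographically smallest index pair), records the merge event and
#' edge, and updates counts additively: `a[w, k] = a[u, k] + a[v, k]`,
#' `m[w] = m[u] + m[v]`, similarities recomputed by the size-normalized
#' rule. If all remaining similarities hit zero before `target_K` is
#' reached, merging stops early with a warning. Final components of the
#' merge-edge graph define the coarse clusters.
#'
#' @param cs a `cluster_similarity` with `S` filled.
#' @param target_K desired number of clusters after merging, in `1..C`.
#' @return object of class `merge_plan`: list with `events` (tibble
#'   `u`, `v`, `similarity` in merge order), `edges` (2-column matrix,
#'   the set P), `components` (list of initial-cluster index sets),
#'   `K`, and `label_map` (initial id -> merged id in `1..K`, merged ids
#'   ordered by smallest member).
#' @export
merge_clusters <- function(cs, target_K) {
  stopifnot(inherits(cs, "cluster_similarity"))
  if (is.null(cs$S)) cs <- similarity_from_counts(cs)
  C <- length(cs$sizes)
  stopifnot(target_K >= 1, target_K <= C)
  a <- cs$A
  m <- cs$sizes
  active <- rep(TRUE, C)
  events_u <- integer(0); events_v <- integer(0); events_s <- numeric(0)
  n_steps <- C - target_K
  for (step in seq_len(n_steps)) {
    act <- which(active)
    s <- a[act, act, drop = FALSE] /
      pmin(matrix(m[act], length(act), length(act)),
           matrix(m[act], length(act), length(act), byrow = TRUE))
    s[lower.tri(s, diag = TRUE)] <- -Inf
    best <- max(s)
    if (best <= 0) {
      warning(sprintf(
        "all remaining similarities are 0 after %d merges; achieved K = %d (target %d)",
        step - 1L, C - step + 1L, target_K))
      break
    }
    # lexicographically smallest (u, v): scan row-major over upper triangle
    hits <- which(s == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    u <- act[hits[1, 1]]; v <- act[hits[1, 2]]
    events_u <- c(events_u, u); events_v <- c(events_v, v)
    events_s <- c(events_s, best)
    # merge v into u
    a[u, ] <- a[u, ] + a[v, ]
    a[, u] <- a[, u] + a[, v]
    a[u, u] <- 0
    m[u] <- m[u] + m[v]
    active[v] <- FALSE
  }
  edges <- cbind(u = events_u, v = events_v)
  comp_id <- .components_from_edges(C, edges)
  # union-by-min makes each component id its smallest member, so sorting
  # the distinct ids orders merged clusters by smallest member cluster id
  label_map <- match(comp_id, sort(unique(comp_id)))
  components <- split(seq_len(C), label_map)
  structure(
    list(
      events = tibble::tibble(u = events_u, v = events_v, similarity = events_s),
      edges = edges,
      components = unname(components),
      K = length(components),
      label_map = label_map
    ),
    class = "merge_plan"
  )
}

# union-find over the merge edges
.components_from_edges <- function(C, edges) {
  parent <- seq_len(C)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      ru <- find(edges[r, 1]); rv <- find(edges[r, 2])
      if (ru != rv) parent[max(ru, rv)] <- min(ru, rv)
    }
  }
  vapply(seq_len(C), find, integer(1))
}

#' Reassign per-cell labels from a merge plan
#'
#' Cells whose initial clusters fall in the same connected component of
#' the merge-edge graph receive one merged label.
#'
#' @param plan a `merge_plan` from [merge_clusters()].
#' @param labels per-cell initial cluster labels in `1..C`.
#' @return integer vector of merged labels in `1..K`.
#' @export
reassign_labels <- function(plan, labels) {
  stopifnot(inherits(plan, "merge_plan"))
  labels <- as.integer(labels)
  if (max(labels) > length(plan$label_map))
    stop("labels reference clusters beyond the merge plan")
  plan$label_map[labels]
}

#' @export
print.merge_plan <- function(x, ...) {
  cat(sprintf("<merge_plan> %d merges -> K = %d components\n",
              nrow(x$events), x$K))
  if (nrow(x$events) > 0) print(utils::head(x$events, 10))
  invisible(x)
}

#' @export
print.cluster_similarity <- function(x, ...) {
  cat(sprintf("<cluster_similarity> C = %d clusters, %d cells, %s\n",
              length(x$sizes), sum(x$sizes),
              if (is.null(x$S)) "counts only" else "similarity filled"))
  invisible(x)
}
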