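#' Integrate multiple batches end to end
#'
#' Runs the five-stage alignment pipeline: (1) preprocessing (filter,
#' library-size/log normalization, HVG selection, per-batch scaling, PCA);
#' (2) over-fine initial clustering on the PCA embedding; (3) intra-batch
#' KNN and inter-batch MNN pair search (cosine distance); (4) cluster
#' similarity, spectral cluster-number inference and greedy hierarchical
#' merging with connected-component label reassignment; (5) hard-triplet
#' metric learning of a low-dimensional batch-corrected embedding
#' supervised by the merged labels.
#'
#' @param x an [sc_data] with raw counts (or normalized values with
#'   `skip_norm = TRUE`).
#' @param n_hvg,n_pca,min_genes,min_cells,target_sum,max_value,skip_norm
#'   preprocessing parameters (see [preprocess()]).
#' @param resolution,init_method,nn_init initial clustering parameters
#'   (see [cluster_init()]).
#' @param k_in,k_bw neighbour counts for the intra-batch KNN and
#'   inter-batch MNN searches.
#' @param n_clusters target number of merged clusters, or `"auto"` to use
#'   the largest spectral eigengap candidate (conservative: fewest merges).
#' @param margin,epochs,batch_size,lr,hidden_dim,embed_dim training
#'   parameters (see [train_embedding()]).
#' @param final_label_mode `"reassigned"` (default) or `"louvain"`.
#' @param seed seed driving every stochastic stage.
#' @param verbose print stage progress.
#' @return object of class `dml_integration`: list with the processed
#'   data, PCA, initial labels, pair sets, similarity object, candidate
#'   cluster numbers, merge plan, merged and final labels, learned
#'   embedding, training log and the full configuration.
#' @examples
#' \donttest{
#' sim <- simulate_batches(n_genes = 400, seed = 1)
#' fit <- integrate_batches(sim, n_hvg = 200, n_pca = 30, epochs = 10)
#' glance(fit)
#' }
#' @export
integrate_batches <- function(x,
                              min_genes = 10, min_cells = 3,
                              target_sum = 1e4, n_hvg = 1000,
                              max_value = 10, n_pca = 100,
                              skip_norm = FALSE,
                              resolution = 3.0, init_method = "louvain",
                              nn_init = 15,
                              k_in = 5, k_bw = 10,
                              n_clusters = "auto",
                              margin = 0.2, epochs = 50, batch_size = 256,
                              lr = 1e-3, hidden_dim = 256, embed_dim = 32,
                              final_label_mode = "reassigned",
                              seed = 0, verbose = FALSE) {
  x <- as_sc_data(x)
  cfg <- list(min_genes = min_genes, min_cells = min_cells,
              target_sum = target_sum, n_hvg = n_hvg, max_value = max_value,
              n_pca = n_pca, skip_norm = skip_norm, resolution = resolution,
              init_method = init_method, nn_init = nn_init, k_in = k_in,
              k_bw = k_bw, n_clusters = n_clusters, margin = margin,
              epochs = epochs, batch_size = batch_size, lr = lr,
              hidden_dim = hidden_dim, embed_dim = embed_dim,
              final_label_mode = final_label_mode, seed = seed)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("stage 1/5: preprocessing (%d cells x %d genes)", nrow(x$values), ncol(x$values))
  prep <- stage("preprocess", preprocess(
    x, min_genes = min_genes, min_cells = min_cells, target_sum = target_sum,
    n_hvg = n_hvg, max_value = max_value, n_pca = n_pca,
    skip_norm = skip_norm, seed = seed))

  say("stage 2/5: initial clustering (resolution %.1f)", resolution)
  init <- stage("init_cluster", cluster_init(
    prep$pca, resolution = resolution, n_neighbors = nn_init,
    method = init_method, seed = seed))
  say("  %d initial clusters", max(init))

  say("stage 3/5: NN pair search (k_in = %d, k_bw = %d)", k_in, k_bw)
  pairs <- stage("nn_graph", {
    intra <- knn_pairs_intra(prep$pca, prep$data$batch, k_in = k_in)
    inter <- if (nlevels(prep$data$batch) > 1) {
      mnn_pairs_inter(prep$pca, prep$data$batch, k_bw = k_bw)
    } else {
      tibble::tibble(i = integer(0), j = integer(0), kind = character(0))
    }
    union_pairs(intra, inter)
  })
  say("  %d ordered pairs (%d intra, %d inter)", nrow(pairs),
      sum(pairs$kind == "intra"), sum(pairs$kind == "inter"))

  say("stage 4/5: similarity + merge")
  cs <- stage("cluster_merge", similarity_from_counts(count_pairs(pairs, init)))
  candidates <- stage("cluster_merge", infer_n_clusters(cs))
  target_K <- if (identical(n_clusters, "auto")) {
    max(candidates)
  } else {
    as.integer(n_clusters)
  }
  say("  candidate cluster numbers: [%s]; merging to K = %d",
      paste(candidates, collapse = ", "), target_K)
  plan <- stage("cluster_merge", merge_clusters(cs, target_K))
  merged <- stage("cluster_merge", reassign_labels(plan, init))

  say("stage 5/5: metric learning (%d epochs)", epochs)
  emb <- stage("triplet_embed", train_embedding(
    prep$data, merged, hidden_dim = hidden_dim, embed_dim = embed_dim,
    margin = margin, epochs = epochs, batch_size = batch_size, lr = lr,
    seed = seed, verbose = verbose))
  final <- stage("triplet_embed", final_labels(
    emb, merged, mode = final_label_mode, seed = seed))

  structure(
    list(data = prep$data, pca = prep$pca, init_labels = as.integer(init),
         pairs = pairs, similarity = cs, candidates = candidates,
         plan = plan, merged_labels = merged, final_labels = final,
         embedding = emb, train_log = attr(emb, "train_log"), config = cfg),
    class = "dml_integration"
  )
}

#' @export
print.dml_integration <- function(x, ...) {
  cat(sprintf(
    "<dml_integration> %d cells, %d batches\n  %d initial clusters -> K = %d merged clusters\n  embedding: %d-d learned; %d NN pairs used\n",
    nrow(x$embedding), nlevels(x$data$batch), max(x$init_labels),
    x$plan$K, ncol(x$embedding), nrow(x$pairs)))
  invisible(x)
}

#' Per-cell summary of an integration fit
#'
#' @param x a `dml_integration`.
#' @param ... unused.
#' @return tibble with one row per cell: ids, batch, truth label (if
#'   available), initial and final cluster, and the first two learned
#'   embedding coordinates.
#' @export
tidy.dml_integration <- function(x, ...) {
  tibble::tibble(
    cell_id = rownames(x$embedding),
    batch = x$data$batch,
    cell_type = if (is.null(x$data$cell_type)) NA else x$data$cell_type,
    init_cluster = x$init_labels,
    cluster = x$final_labels,
    dml1 = x$embedding[, 1],
    dml2 = x$embedding[, 2]
  )
}

#' One-row summary of an integration fit
#'
#' @inheritParams tidy.dml_integration
#' @return one-row tibble: cell/gene counts, initial and merged cluster
#'   numbers, pair counts and the final-epoch training loss.
#' @export
glance.dml_integration <- function(x, ...) {
  tl <- x$train_log
  tibble::tibble(
    n_cells = nrow(x$embedding),
    n_batches = nlevels(x$data$batch),
    n_hvg = ncol(x$data$values),
    n_init_clusters = max(x$init_labels),
    k_merged = x$plan$K,
    n_pairs = nrow(x$pairs),
    final_loss = tl$mean_loss[nrow(tl)]
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot an integration fit
#'
#' Scatter plot of the first two principal components of the learned
#' embedding, coloured by cluster, batch or (if available) true cell
#' type.
#'
#' @param x a `dml_integration`.
#' @param colour one of `"cluster"`, `"batch"`, `"cell_type"`.
#' @return a ggplot object.
#' @export
plot_integration <- function(x, colour = c("cluster", "batch", "cell_type")) {
  colour <- match.arg(colour)
  emb <- unclass(x$embedding)
  pc <- pca_embed(emb, n_pca = 2)
  df <- data.frame(
    x = pc[, 1], y = pc[, 2],
    cluster = factor(x$final_labels),
    batch = x$data$batch,
    cell_type = if (is.null(x$data$cell_type)) factor(NA) else x$data$cell_type
  )
  df$col <- df[[colour]]
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = col)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::labs(x = "embedding PC1", y = "embedding PC2", colour = colour) +
    ggplot2::theme_minimal()
}

#' @rdname plot_integration
#' @param object a `dml_integration`.
#' @param ... passed to [plot_integration()].
#' @export
autoplot.dml_integration <- function(object, ...) plot_integration(object, ...)
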