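#' Filter low-quality cells and rarely expressed genes
#'
#' Cells are filtered first (fewer than `min_genes` detected genes), then
#' genes (detected in fewer than `min_cells` of the remaining cells). Gene
#' filtering can re-lower the detected-gene count of some cells; the cell
#' filter is deliberately not re-applied.
#'
#' @param x an [sc_data] holding raw counts.
#' @param min_genes minimum number of genes with nonzero counts per cell.
#' @param min_cells minimum number of cells with nonzero counts per gene.
#' @return The filtered [sc_data].
#' @export
filter_cells_genes <- function(x, min_genes = 10, min_cells = 3) {
  x <- as_sc_data(x)
  if (x$normalized) stop("filter_cells_genes expects raw counts")
  stopifnot(min_genes >= 0, min_cells >= 0)
  keep_cells <- rowSums(x$values > 0) >= min_genes
  if (!any(keep_cells)) stop("empty-after-filter: all cells removed")
  x <- subset_sc(x, cells = which(keep_cells))
  keep_genes <- colSums(x$values > 0) >= min_cells
  if (!any(keep_genes)) stop("empty-after-filter: all genes removed")
  subset_sc(x, genes = which(keep_genes))
}

#' Library-size normalize and log-transform
#'
#' Scales each cell to a common total count (`target_sum`, 10,000 by
#' default) and applies `log(1 + y)`.
#'
#' @param x an [sc_data] holding raw counts with positive cell totals.
#' @param target_sum per-cell total after normalization.
#' @return The [sc_data] with `values = log1p(target_sum * x / rowSums(x))`
#'   and the `normalized` flag set.
#' @export
normalize_log <- function(x, target_sum = 1e4) {
  x <- as_sc_data(x)
  tot <- rowSums(x$values)
  if (any(tot <= 0)) {
    bad <- rownames(x$values)[which(tot <= 0)[1]]
    stop(sprintf("cell '%s' has zero total counts; filter cells first", bad))
  }
  x$values <- log1p(x$values * (target_sum / tot))
  x$normalized <- TRUE
  x
}

# normalized dispersion per gene, mean-binned z-score on log dispersion
# (the "seurat" flavour); operates on one log-normalized submatrix
.norm_dispersion <- function(vals, n_bins = 20) {
  ex <- expm1(vals)
  mu <- colMeans(ex)
  v <- apply(ex, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  log_mu <- log1p(mu)
  log_disp <- ifelse(disp > 0, log(disp), NA_real_)
  bins <- cut(log_mu, breaks = n_bins, include.lowest = TRUE)
  nd <- rep(-Inf, length(mu))
  for (b in levels(bins)) {
    in_bin <- which(bins == b & !is.na(log_disp))
    if (length(in_bin) == 0) next
    m <- mean(log_disp[in_bin])
    s <- stats::sd(log_disp[in_bin])
    if (!is.finite(s) || s == 0) s <- 1
    nd[in_bin] <- (log_disp[in_bin] - m) / s
  }
  nd
}

#' Select highly variable genes
#'
#' Ranks genes by the mean-binned normalized-dispersion criterion computed
#' on the exponentiated log-normalized values. With `per_batch = TRUE`
#' (default) dispersions are computed within each batch, genes are scored
#' by the number of batches whose top-`n_hvg` list contains them, and ties
#' are broken by the median normalized dispersion across batches.
#'
#' @param x a log-normalized [sc_data].
#' @param n_hvg number of genes to keep.
#' @param per_batch compute the criterion within each batch (recommended
#'   for integration) or jointly.
#' @param n_bins number of mean bins for dispersion normalization.
#' @return The [sc_data] restricted to the selected genes, with the
#'   selection table in `attr(, "hvg")`.
#' @export
select_hvgs <- function(x, n_hvg = 1000, per_batch = TRUE, n_bins = 20) {
  x <- as_sc_data(x)
  if (!x$normalized) stop("select_hvgs expects log-normalized values")
  p <- ncol(x$values)
  if (n_hvg < 1 || n_hvg > p)
    stop(sprintf("n_hvg must be in 1..%d", p))
  if (per_batch && nlevels(x$batch) > 1) {
    nd <- sapply(levels(x$batch), function(b) {
      .norm_dispersion(x$values[x$batch == b, , drop = FALSE], n_bins)
    })
    in_top <- apply(nd, 2, function(col) rank(-col, ties.method = "first") <= n_hvg)
    n_sel <- rowSums(in_top)
    med_nd <- apply(nd, 1, stats::median)
    ord <- order(-n_sel, -med_nd, seq_len(p))
  } else {
    nd <- .norm_dispersion(x$values, n_bins)
    ord <- order(-nd, seq_len(p))
    n_sel <- NULL
    med_nd <- nd
  }
  sel <- sort(ord[seq_len(n_hvg)])
  out <- subset_sc(x, genes = sel)
  attr(out, "hvg") <- tibble::tibble(
    gene = colnames(x$values)[sel],
    median_norm_dispersion = med_nd[sel],
    n_batches_selected = if (is.null(n_sel)) NA_integer_ else n_sel[sel]
  )
  out
}

#' Per-batch z-scaling with truncation
#'
#' Within each batch, centers every gene to mean 0 and scales it to unit
#' variance (constant genes become 0), then truncates values to
#' `[-max_value, max_value]`.
#'
#' @param x a log-normalized [sc_data] (typically HVG-restricted).
#' @param max_value truncation bound for the z-scores.
#' @return The scaled [sc_data] (`scaled` flag set).
#' @export
scale_per_batch <- function(x, max_value = 10) {
  x <- as_sc_data(x)
  if (!x$normalized) stop("scale_per_batch expects log-normalized values")
  for (b in levels(x$batch)) {
    idx <- which(x$batch == b)
    sub <- x$values[idx, , drop = FALSE]
    if (length(idx) == 1) {
      warning(sprintf("batch '%s' has a single cell; variance undefined, scaling by 1", b))
      x$values[idx, ] <- sub - sub  # centered single cell is 0
      next
    }
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    x$values[idx, ] <- sweep(sweep(sub, 2, mu), 2, sdv, "/")
  }
  x$values[x$values > max_value] <- max_value
  x$values[x$values < -max_value] <- -max_value
  x$scaled <- TRUE
  x
}

#' PCA embedding of the scaled matrix
#'
#' Exact singular-value decomposition of the column-centered matrix; the
#' leading `n_pca` principal-component scores are returned. Component signs
#' are fixed deterministically (largest-magnitude loading positive).
#'
#' @param x a scaled [sc_data] (or any numeric matrix, cells x features).
#' @param n_pca number of components; must not exceed `min(cells - 1, genes)`.
#' @param seed kept for interface stability; the exact solver is
#'   deterministic regardless.
#' @return A cells x `n_pca` numeric matrix with `attr(, "space") = "pca"`.
#' @export
pca_embed <- function(x, n_pca = 100, seed = 0) {
  vals <- if (inherits(x, "sc_data")) x$values else as.matrix(x)
  n <- nrow(vals); p <- ncol(vals)
  max_pc <- min(n - 1, p)
  if (n_pca > max_pc)
    stop(sprintf("n_pca too large; maximum admissible is %d", max_pc))
  set.seed(as.integer(seed))
  ctr <- sweep(vals, 2, colMeans(vals))
  sv <- svd(ctr, nu = n_pca, nv = n_pca)
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sv$u %*% diag(sv$d[seq_len(n_pca)], n_pca) %*% diag(flip, n_pca)
  rownames(scores) <- rownames(vals)
  colnames(scores) <- paste0("PC", seq_len(n_pca))
  attr(scores, "space") <- "pca"
  scores
}

#' Run the full preprocessing chain
#'
#' filter -> normalize/log -> HVG selection -> per-batch scaling -> PCA.
#' `skip_norm = TRUE` trusts already-normalized input and bypasses the
#' filter and normalization stages.
#'
#' @inheritParams filter_cells_genes
#' @inheritParams select_hvgs
#' @inheritParams scale_per_batch
#' @inheritParams pca_embed
#' @param skip_norm input is already log-normalized.
#' @return list with elements `data` (scaled HVG [sc_data]) and `pca`
#'   (embedding matrix).
#' @export
preprocess <- function(x, min_genes = 10, min_cells = 3, target_sum = 1e4,
                       n_hvg = 1000, per_batch = TRUE, max_value = 10,
                       n_pca = 100, skip_norm = FALSE, seed = 0) {
  x <- as_sc_data(x)
  if (!skip_norm) {
    x <- filter_cells_genes(x, min_genes, min_cells)
    x <- normalize_log(x, target_sum)
  } else {
    x$normalized <- TRUE
  }
  x <- select_hvgs(x, n_hvg = min(n_hvg, ncol(x$values)), per_batch = per_batch)
  x <- scale_per_batch(x, max_value = max_value)
  emb <- pca_embed(x, n_pca = min(n_pca, nrow(x$values) - 1, ncol(x$values)),
                   seed = seed)
  list(data = x, pca = emb)
}
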