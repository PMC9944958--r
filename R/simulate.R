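#' Simulate multi-batch scRNA-seq counts with known ground truth
#'
#' Generates negative-binomial counts in the splatter family: log-normal
#' baseline gene means, per-type differential-expression factors,
#' multiplicative log-normal per-batch gene effects, and log-normal library
#' sizes. The default design is the benchmark used throughout this package:
#' 3 batches x 6 cell types (~2,880 cells x 2,000 genes) with one rare type
#' at ~2% abundance and one type present in a single batch only, under a
#' batch effect strong enough that a Louvain clustering of the uncorrected
#' PCA splits cell types by batch.
#'
#' @param n_batches,n_types design dimensions (ignored when
#'   `cells_per_type_per_batch` is given).
#' @param cells_per_type_per_batch integer matrix, types x batches; zeros
#'   encode batch-absent types. `NULL` uses the default design described
#'   above when `n_batches == 3 && n_types == 6`, otherwise 200 cells per
#'   type per batch.
#' @param n_genes number of genes.
#' @param de_frac fraction of genes differentially expressed per type.
#' @param de_lfc log fold change magnitude of type DE factors (natural log).
#' @param batch_effect_sd sd of per-batch per-gene log-normal effects; 0
#'   disables the batch effect.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param lib_size_mean,lib_size_sd log-normal library-size parameters
#'   (mean on the natural scale, sd on the log scale).
#' @param hierarchy optional data.frame with columns `parent` (type index)
#'   and `scale` (subtype effect scale, in (0,1) relative to `de_lfc`);
#'   each row adds one subtype of the given parent type. When present, the
#'   leaf labels are subtypes (e.g. `"T1.s1"`) and
#'   `cells_per_type_per_batch` refers to leaf types in row order.
#' @param seed RNG seed; output is fully determined by the arguments.
#'
#' @return An [sc_data] with raw counts, `batch` and `cell_type` populated.
#' @examples
#' sim <- simulate_batches(n_genes = 300, seed = 1)
#' table(sim$cell_type, sim$batch)
#' @export
simulate_batches <- function(n_batches = 3, n_types = 6,
                             cells_per_type_per_batch = NULL,
                             n_genes = 2000,
                             de_frac = 0.1, de_lfc = 1.2,
                             batch_effect_sd = 2.0,
                             dispersion = 0.15,
                             lib_size_mean = 2500, lib_size_sd = 0.25,
                             hierarchy = NULL, seed = 1) {
  set.seed(as.integer(seed))

  # leaf type structure
  if (!is.null(hierarchy)) {
    hierarchy <- as.data.frame(hierarchy)
    if (!all(c("parent", "scale") %in% names(hierarchy)))
      stop("hierarchy needs columns 'parent' and 'scale'")
    if (any(hierarchy$parent < 1 | hierarchy$parent > n_types))
      stop("hierarchy references a parent type outside 1..n_types")
    if (any(hierarchy$scale >= 1))
      warning("subtype_effect_scale >= 1: subtype separation may exceed type separation")
  }

  base_mean <- exp(stats::rnorm(n_genes, mean = 0, sd = 1))

  # per-type expected expression proportions
  type_prop <- matrix(0, n_types, n_genes)
  n_de <- max(1L, round(de_frac * n_genes))
  de_sets <- vector("list", n_types)
  for (t in seq_len(n_types)) {
    idx <- sample.int(n_genes, n_de)
    fac <- rep(1, n_genes)
    fac[idx] <- exp(de_lfc * sample(c(-1, 1), n_de, replace = TRUE))
    de_sets[[t]] <- idx
    m <- base_mean * fac
    type_prop[t, ] <- m / sum(m)
  }

  # expand to leaves (subtypes share the parent profile plus smaller DE)
  if (!is.null(hierarchy)) {
    leaf_prop <- matrix(0, nrow(hierarchy), n_genes)
    leaf_names <- character(nrow(hierarchy))
    sub_counter <- integer(n_types)
    n_sub_de <- max(1L, round(de_frac * n_genes / 2))
    for (r in seq_len(nrow(hierarchy))) {
      p_t <- hierarchy$parent[r]
      sub_counter[p_t] <- sub_counter[p_t] + 1L
      idx <- sample.int(n_genes, n_sub_de)
      fac <- rep(1, n_genes)
      fac[idx] <- exp(hierarchy$scale[r] * de_lfc *
                        sample(c(-1, 1), n_sub_de, replace = TRUE))
      m <- type_prop[p_t, ] * fac
      leaf_prop[r, ] <- m / sum(m)
      leaf_names[r] <- sprintf("T%d.s%d", p_t, sub_counter[p_t])
    }
    type_prop <- leaf_prop
    type_names <- leaf_names
  } else {
    type_names <- paste0("T", seq_len(n_types))
  }
  n_leaf <- nrow(type_prop)

  if (is.null(cells_per_type_per_batch)) {
    if (is.null(hierarchy) && n_batches == 3 && n_types == 6) {
      # benchmark design: 4 shared types, one batch-unique type (T5, batch 1
      # only), one rare type (T6, ~2% of cells)
      cells_per_type_per_batch <- rbind(
        matrix(220L, 4, 3),
        c(180L, 0L, 0L),
        c(20L, 20L, 20L)
      )
    } else {
      cells_per_type_per_batch <- matrix(200L, n_leaf, n_batches)
    }
  }
  cells_per_type_per_batch <- as.matrix(cells_per_type_per_batch)
  if (nrow(cells_per_type_per_batch) != n_leaf ||
      ncol(cells_per_type_per_batch) != n_batches)
    stop("cells_per_type_per_batch must be n_types(/leaves) x n_batches")

  # per-batch multiplicative gene effects, shared by all cells in the batch
  batch_fac <- matrix(exp(stats::rnorm(n_batches * n_genes, 0, batch_effect_sd)),
                      n_batches, n_genes)

  n_cells <- sum(cells_per_type_per_batch)
  counts <- matrix(0L, n_cells, n_genes)
  batch <- character(n_cells)
  truth <- character(n_cells)
  size <- if (dispersion > 0) 1 / dispersion else Inf
  row <- 0L
  for (b in seq_len(n_batches)) {
    for (t in seq_len(n_leaf)) {
      nc <- cells_per_type_per_batch[t, b]
      if (nc == 0) next
      q <- type_prop[t, ] * batch_fac[b, ]
      q <- q / sum(q)
      libs <- stats::rlnorm(nc, meanlog = log(lib_size_mean), sdlog = lib_size_sd)
      for (ci in seq_len(nc)) {
        mu <- libs[ci] * q
        counts[row + ci, ] <- if (is.finite(size)) {
          stats::rnbinom(n_genes, mu = mu, size = size)
        } else {
          stats::rpois(n_genes, lambda = mu)
        }
      }
      batch[row + seq_len(nc)] <- paste0("B", b)
      truth[row + seq_len(nc)] <- type_names[t]
      row <- row + nc
    }
  }
  sc_data(counts,
          batch = factor(batch, levels = paste0("B", seq_len(n_batches))),
          cell_type = factor(truth, levels = type_names),
          cell_ids = paste0("cell", seq_len(n_cells)))
}

#' Simulate nested (hierarchical) cell types
#'
#' Convenience wrapper around [simulate_batches()] producing parent types
#' split into subtypes whose profiles share the parent DE genes plus
#' smaller-effect subtype-specific genes, so same-parent subtypes sit
#' closer together than different parents in expectation.
#'
#' @param n_parents number of parent types.
#' @param subtypes_per_parent subtypes within each parent.
#' @param subtype_effect_scale subtype DE effect relative to the parent
#'   effect (must be < 1 for the hierarchy to be respected).
#' @param cells_per_subtype_per_batch cells for every leaf in every batch.
#' @inheritParams simulate_batches
#' @return An [sc_data] with leaf (subtype) labels such as `"T1.s2"`.
#' @export
simulate_nested <- function(n_parents = 2, subtypes_per_parent = 2,
                            subtype_effect_scale = 0.35,
                            n_batches = 2, n_genes = 500,
                            cells_per_subtype_per_batch = 60,
                            de_frac = 0.1, de_lfc = 1.2,
                            batch_effect_sd = 0.4, dispersion = 0.15,
                            lib_size_mean = 2500, lib_size_sd = 0.25,
                            seed = 1) {
  hierarchy <- data.frame(
    parent = rep(seq_len(n_parents), each = subtypes_per_parent),
    scale = subtype_effect_scale
  )
  n_leaf <- nrow(hierarchy)
  simulate_batches(
    n_batches = n_batches, n_types = n_parents,
    cells_per_type_per_batch = matrix(cells_per_subtype_per_batch,
                                      n_leaf, n_batches),
    n_genes = n_genes, de_frac = de_frac, de_lfc = de_lfc,
    batch_effect_sd = batch_effect_sd, dispersion = dispersion,
    lib_size_mean = lib_size_mean, lib_size_sd = lib_size_sd,
    hierarchy = hierarchy, seed = seed
  )
}

#' Parent type of nested simulation labels
#'
#' Maps leaf labels of the form `"T<p>.s<j>"` back to their parent `"T<p>"`.
#'
#' @param labels factor or character vector of leaf labels.
#' @return character vector of parent labels.
#' @export
parent_type <- function(labels) {
  sub("\\.s[0-9]+$", "", as.character(labels))
}
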