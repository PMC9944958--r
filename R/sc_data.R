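#' Single-cell expression container
#'
#' A light container for a cells x genes expression matrix with per-cell
#' batch labels and (optionally) ground-truth cell-type labels. Values are
#' raw counts until [normalize_log()] is applied, after which the
#' `normalized` flag is set and downstream stages refuse raw-only inputs.
#'
#' @param values numeric matrix, cells in rows, genes in columns.
#' @param batch per-cell batch labels (coerced to factor), length `nrow(values)`.
#' @param cell_type optional per-cell ground-truth labels (factor or NULL).
#' @param gene_ids,cell_ids optional unique identifiers; defaults to
#'   dimnames or generated ids.
#' @param normalized logical; has library-size/log normalization been applied?
#' @param scaled logical; has per-batch z-scaling been applied?
#'
#' @return An object of class `sc_data`: a list with elements `values`,
#'   `batch`, `cell_type`, `normalized`, `scaled`.
#' @export
sc_data <- function(values, batch, cell_type = NULL, gene_ids = NULL,
                    cell_ids = NULL, normalized = FALSE, scaled = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(p))
  }
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (length(batch) != n) stop("batch must have one label per cell")
  batch <- droplevels(as.factor(batch))
  if (!is.null(cell_type)) {
    if (length(cell_type) != n) stop("cell_type must have one label per cell")
    cell_type <- droplevels(as.factor(cell_type))
  }
  if (!normalized && any(values < 0)) {
    stop("raw count matrix must be non-negative")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, batch = batch, cell_type = cell_type,
         normalized = normalized, scaled = scaled),
    class = "sc_data"
  )
}

#' @export
print.sc_data <- function(x, ...) {
  cat(sprintf("<sc_data> %d cells x %d genes\n", nrow(x$values), ncol(x$values)))
  cat(sprintf("  batches:   %s\n",
              paste(sprintf("%s(%d)", levels(x$batch), tabulate(x$batch)),
                    collapse = " ")))
  if (!is.null(x$cell_type)) {
    cat(sprintf("  cell types: %d (%s)\n", nlevels(x$cell_type),
                paste(utils::head(levels(x$cell_type), 8), collapse = ", ")))
  }
  cat(sprintf("  normalized: %s, scaled: %s\n", x$normalized, x$scaled))
  invisible(x)
}

#' @export
dim.sc_data <- function(x) dim(x$values)

# subset an sc_data by cell and/or gene index, keeping labels in step
subset_sc <- function(x, cells = NULL, genes = NULL) {
  if (!is.null(cells)) {
    x$values <- x$values[cells, , drop = FALSE]
    x$batch <- droplevels(x$batch[cells])
    if (!is.null(x$cell_type)) x$cell_type <- droplevels(x$cell_type[cells])
  }
  if (!is.null(genes)) {
    x$values <- x$values[, genes, drop = FALSE]
  }
  x
}

as_sc_data <- function(x) {
  if (inherits(x, "sc_data")) return(x)
  stop("expected an 'sc_data' object; see sc_data() or read_mtx_dir()")
}
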