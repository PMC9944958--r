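#' Read a 10x-style MTX directory
#'
#' Expects `matrix.mtx` (genes x cells, MatrixMarket), `barcodes.tsv` and
#' `features.tsv` (or `genes.tsv`); an optional `metadata.tsv` with a
#' header row supplies per-cell annotations, from which the batch and
#' truth labels are taken by column name.
#'
#' @param dir directory path.
#' @param batch_key,label_key column names in `metadata.tsv` holding the
#'   batch and (optional) cell-type labels.
#' @param batch explicit per-cell batch labels, overriding `batch_key`
#'   (required when no metadata file exists).
#' @return an [sc_data] with raw counts.
#' @export
read_mtx_dir <- function(dir, batch_key = "batch", label_key = NULL,
                         batch = NULL) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop(sprintf("no matrix.mtx under '%s'", dir))
  m <- Matrix::readMM(mtx)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feat_file <- if (file.exists(file.path(dir, "features.tsv")))
    file.path(dir, "features.tsv") else file.path(dir, "genes.tsv")
  feats <- utils::read.delim(feat_file, header = FALSE,
                             stringsAsFactors = FALSE)[, 1]
  vals <- t(as.matrix(m))  # to cells x genes
  cell_type <- NULL
  meta_file <- file.path(dir, "metadata.tsv")
  if (file.exists(meta_file)) {
    meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
    if (is.null(batch)) {
      if (!batch_key %in% names(meta))
        stop(sprintf("metadata.tsv has no column '%s'", batch_key))
      batch <- meta[[batch_key]]
    }
    if (!is.null(label_key) && label_key %in% names(meta))
      cell_type <- meta[[label_key]]
  }
  if (is.null(batch))
    stop("no batch labels: provide 'batch' or a metadata.tsv with batch_key")
  sc_data(vals, batch = batch, cell_type = cell_type,
          gene_ids = feats, cell_ids = barcodes)
}

#' Write an [sc_data] as an MTX directory
#'
#' Writes `matrix.mtx` (genes x cells), `barcodes.tsv`, `genes.tsv` and a
#' `metadata.tsv` with the batch (and cell-type, if present) labels.
#'
#' @param x an [sc_data].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx_dir <- function(x, dir) {
  x <- as_sc_data(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(x$values), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$values), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(x$values), file.path(dir, "genes.tsv"))
  meta <- data.frame(cell_id = rownames(x$values), batch = x$batch)
  if (!is.null(x$cell_type)) meta$cell_type <- x$cell_type
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a delimited expression table
#'
#' @param file path to a delimited text file with header and row names
#'   (cells x genes, or genes x cells with `transpose = TRUE`).
#' @param batch per-cell batch labels (required).
#' @param cell_type optional per-cell truth labels.
#' @param transpose input is genes x cells.
#' @param sep field separator.
#' @return an [sc_data].
#' @export
read_delim_matrix <- function(file, batch, cell_type = NULL,
                              transpose = FALSE, sep = "\t") {
  tab <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE)
  vals <- as.matrix(tab)
  if (transpose) vals <- t(vals)
  sc_data(vals, batch = batch, cell_type = cell_type)
}

#' Read an h5ad-dialect HDF5 single-cell container
#'
#' Minimal reader for the standard layout: `X` as a dense dataset or a
#' compressed-sparse group (`data`/`indices`/`indptr` with a `shape`
#' attribute), `obs`/`var` groups with an `_index` column and per-cell
#' annotation columns stored as plain datasets or categorical groups
#' (`categories` + `codes`). Requires the rhdf5 package.
#'
#' @param path h5ad file path.
#' @param batch_key obs column holding the batch label.
#' @param label_key optional obs column holding the truth label.
#' @param normalized flag the values as already normalized.
#' @return an [sc_data].
#' @export
read_h5ad <- function(path, batch_key = "batch", label_key = NULL,
                      normalized = FALSE) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("read_h5ad requires the 'rhdf5' package")
  h5 <- rhdf5::h5ls(path)
  read_obs_col <- function(group, col) {
    entry <- h5[h5$group == paste0("/", group) & h5$name == col, ]
    if (nrow(entry) == 0) return(NULL)
    obj <- rhdf5::h5read(path, paste0(group, "/", col))
    if (is.list(obj) && all(c("categories", "codes") %in% names(obj))) {
      as.vector(obj$categories)[as.integer(obj$codes) + 1L]
    } else {
      as.vector(obj)
    }
  }
  x_is_group <- any(h5$group == "/X")
  if (x_is_group) {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    attrs <- rhdf5::h5readAttributes(path, "X")
    shape <- as.integer(attrs$shape)  # (n_obs, n_var)
    enc <- if (!is.null(attrs$`encoding-type`)) attrs$`encoding-type` else "csr_matrix"
    if (grepl("csr", enc)) {
      m <- Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = data,
                                dims = rev(shape))  # vars x obs
      vals <- t(as.matrix(m))
    } else {
      m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                dims = shape)
      vals <- as.matrix(m)
    }
  } else {
    vals <- rhdf5::h5read(path, "X")
    # HDF5 is row-major; rhdf5 returns the transposed (n_var x n_obs) array
    vals <- t(as.matrix(vals))
  }
  obs_idx <- read_obs_col("obs", "_index")
  var_idx <- read_obs_col("var", "_index")
  batch <- read_obs_col("obs", batch_key)
  if (is.null(batch))
    stop(sprintf("obs column '%s' not found in %s", batch_key, path))
  cell_type <- if (!is.null(label_key)) read_obs_col("obs", label_key) else NULL
  sc_data(vals, batch = batch, cell_type = cell_type,
          gene_ids = var_idx, cell_ids = obs_idx, normalized = normalized)
}

#' Write an [sc_data] to a minimal h5ad-dialect file
#'
#' Writes `X` dense (cells x genes on read-back with this package's
#' reader and with Python readers), `obs` with `_index`, `batch` and any
#' cell-type labels, and `var` with `_index`. Requires rhdf5.
#'
#' @param x an [sc_data].
#' @param path output file path (overwritten).
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(x, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("write_h5ad requires the 'rhdf5' package")
  x <- as_sc_data(x)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  # store transposed so the row-major file holds obs-major data
  rhdf5::h5write(t(x$values), path, "X")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(rownames(x$values), path, "obs/_index")
  rhdf5::h5write(as.character(x$batch), path, "obs/batch")
  if (!is.null(x$cell_type))
    rhdf5::h5write(as.character(x$cell_type), path, "obs/cell_type")
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(colnames(x$values), path, "var/_index")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Export NN pairs as a two-column TSV
#'
#' @param pairs pair tibble.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, file) {
  utils::write.table(pairs, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
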