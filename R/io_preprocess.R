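#' Construct a validated count matrix
#'
#' The basic container used throughout the package: a dense matrix of
#' non-negative integer UMI counts with cells/barcodes in rows and genes in
#' columns. Validation enforces finiteness, non-negativity and unique
#' identifiers.
#'
#' @param counts numeric matrix (cells x genes), non-negative and finite.
#' @param barcodes character vector of row identifiers (default taken from
#'   rownames or generated).
#' @param genes character vector of column identifiers (default taken from
#'   colnames or generated).
#' @return an object of class `count_matrix` (a matrix with `barcodes` and
#'   `genes` in its dimnames).
#' @export
count_matrix <- function(counts, barcodes = NULL, genes = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(barcodes)) {
    barcodes <- rownames(counts)
    if (is.null(barcodes)) barcodes <- paste0("cell", seq_len(nrow(counts)))
  }
  if (is.null(genes)) {
    genes <- colnames(counts)
    if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(counts)))
  }
  if (length(barcodes) != nrow(counts) || length(genes) != ncol(counts)) {
    dv_stop("barcode/gene identifier lengths do not match matrix dimensions",
            "dv_validation_error")
  }
  if (anyDuplicated(barcodes)) {
    dv_stop("duplicate barcodes in count matrix", "dv_validation_error")
  }
  if (anyDuplicated(genes)) {
    dv_stop("duplicate gene identifiers in count matrix", "dv_validation_error")
  }
  if (any(!is.finite(counts))) {
    dv_stop("count matrix contains non-finite entries", "dv_validation_error")
  }
  if (any(counts < 0)) {
    dv_stop("count matrix contains negative entries", "dv_validation_error")
  }
  dimnames(counts) <- list(as.character(barcodes), as.character(genes))
  class(counts) <- c("count_matrix", "matrix", "array")
  counts
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d barcodes x %d genes; total counts %.0f\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Load a raw count matrix
#'
#' Reads raw, un-normalized UMI counts from a 10x-style MTX directory
#' (`matrix.mtx` + `barcodes.tsv` + `features.tsv`/`genes.tsv`), a 10x-style
#' HDF5 container, or a dense CSV with a header row of gene names and one
#' row per barcode. Orientation of MTX/HDF5 data (genes x cells on disk) is
#' auto-detected by matching dimensions against the feature list; the
#' returned matrix always has genes as columns.
#'
#' @param path file (csv/h5) or directory (mtx) to read.
#' @param format one of `"mtx_dir"`, `"h5_container"`, `"csv"`; default
#'   guesses from `path`.
#' @return a [count_matrix()].
#' @export
load_counts <- function(path,
                        format = c("auto", "mtx_dir", "h5_container", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx_dir"
      else if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "h5_container"
      else "csv"
  }
  if (format != "mtx_dir" && !file.exists(path)) {
    dv_stop(paste0("input file not found: ", path), "dv_io_error")
  }
  switch(format,
    mtx_dir = load_counts_mtx(path),
    h5_container = load_counts_h5(path),
    csv = load_counts_csv(path)
  )
}

find_one <- function(dir, patterns, what) {
  for (p in patterns) {
    hit <- list.files(dir, pattern = p, full.names = TRUE)
    if (length(hit)) return(hit[[1L]])
  }
  dv_stop(sprintf("no %s file found in %s (looked for %s)",
                  what, dir, paste(patterns, collapse = ", ")),
          "dv_io_error")
}

load_counts_mtx <- function(dir) {
  if (!dir.exists(dir)) {
    dv_stop(paste0("MTX directory not found: ", dir), "dv_io_error")
  }
  mtx <- find_one(dir, c("^matrix\\.mtx$", "\\.mtx$"), "matrix (.mtx)")
  bc <- find_one(dir, c("^barcodes\\.tsv$", "barcodes"), "barcodes")
  ft <- find_one(dir, c("^features\\.tsv$", "^genes\\.tsv$", "features", "genes"),
                 "features/genes")
  m <- as.matrix(Matrix::readMM(mtx))
  barcodes <- read.delim(bc, header = FALSE)[[1L]]
  feat <- read.delim(ft, header = FALSE)
  genes <- feat[[min(2L, ncol(feat))]]  # 10x features.tsv: id, symbol, type
  if (anyDuplicated(genes)) genes <- feat[[1L]]
  # on-disk 10x convention is genes x cells; accept either orientation
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    m <- t(m)
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(genes))) {
    dv_stop("matrix dimensions match neither barcodes x features nor features x barcodes",
            "dv_io_error")
  }
  validate_loaded(m)
  count_matrix(m, barcodes = barcodes, genes = genes)
}

load_counts_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    dv_stop("reading HDF5 containers requires the rhdf5 package", "dv_io_error")
  }
  ls <- rhdf5::h5ls(path)
  grp <- unique(ls$group[ls$name == "data"])
  if (!length(grp)) dv_stop("no CSC count group found in HDF5 file", "dv_io_error")
  g <- sub("^/", "", grp[[1L]])
  rd <- function(n) rhdf5::h5read(path, paste0(g, "/", n))
  shape <- as.integer(rd("shape"))
  m <- Matrix::sparseMatrix(
    i = as.integer(rd("indices")) + 1L, p = as.integer(rd("indptr")),
    x = as.numeric(rd("data")), dims = shape
  )
  m <- as.matrix(m)
  genes <- tryCatch(as.character(rd("features/name")),
                    error = function(e) tryCatch(as.character(rd("genes")),
                                                 error = function(e) NULL))
  if (is.null(genes)) genes <- tryCatch(as.character(rd("features/id")),
                                        error = function(e) NULL)
  barcodes <- tryCatch(as.character(rd("barcodes")), error = function(e) NULL)
  if (!is.null(genes) && nrow(m) == length(genes)) m <- t(m)
  validate_loaded(m)
  count_matrix(m, barcodes = barcodes, genes = genes)
}

load_counts_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  first_is_id <- ncol(df) > 1L && !is.numeric(df[[1L]])
  barcodes <- if (first_is_id) as.character(df[[1L]]) else NULL
  if (first_is_id) df <- df[, -1L, drop = FALSE]
  m <- as.matrix(df)
  if (!is.numeric(m)) dv_stop("CSV contains non-numeric entries", "dv_validation_error")
  validate_loaded(m)
  m <- round(m)  # raw UMI counts are integral; tolerate float storage
  count_matrix(m, barcodes = barcodes, genes = colnames(df))
}

validate_loaded <- function(m) {
  if (any(!is.finite(m))) {
    dv_stop("counts contain non-finite entries", "dv_validation_error")
  }
  if (any(m < 0)) {
    dv_stop("counts contain negative entries", "dv_validation_error")
  }
  invisible(TRUE)
}

#' Write a count matrix as a 10x-style MTX directory
#'
#' Writes `matrix.mtx` (genes x cells, the on-disk 10x convention),
#' `barcodes.tsv` and `features.tsv`. Counts are rounded to integers.
#'
#' @param x a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(unclass(x)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(id = colnames(x), name = colnames(x)),
              file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Remove genes observed in too few cells
#'
#' Drops genes whose zero fraction across rows exceeds `max_zero_fraction`
#' (a gene zero in more than 99% of rows is removed by default; a gene zero
#' in exactly 99% is kept).
#'
#' @param x a [count_matrix()] (or plain matrix).
#' @param max_zero_fraction genes with zero-fraction strictly greater than
#'   this are removed; in (0, 1].
#' @return the filtered [count_matrix()].
#' @export
filter_sparse_genes <- function(x, max_zero_fraction = 0.99) {
  stopifnot(max_zero_fraction > 0, max_zero_fraction <= 1)
  zf <- colMeans(unclass(x) == 0)
  keep <- zf <= max_zero_fraction
  if (!any(keep)) {
    dv_stop("all genes removed: matrix is too sparse for doublet annotation",
            "dv_validation_error")
  }
  count_matrix(unclass(x)[, keep, drop = FALSE],
               barcodes = rownames(x), genes = colnames(x)[keep])
}

#' Keep the most variable genes
#'
#' Retains the `n_top` genes with the largest per-gene variance of the raw
#' counts, preserving the original column order; ties are broken in favor
#' of the earlier column.
#'
#' @param x a [count_matrix()].
#' @param n_top number of genes to keep (default 2000); capped at the number
#'   of genes present.
#' @return the reduced [count_matrix()].
#' @export
select_variable_genes <- function(x, n_top = 2000L) {
  stopifnot(n_top >= 1L)
  m <- unclass(x)
  v <- apply(m, 2L, var)
  n_keep <- min(as.integer(n_top), ncol(m))
  ord <- order(-v, seq_along(v))[seq_len(n_keep)]  # ties: first column wins
  keep <- sort(ord)                                # preserve original order
  count_matrix(m[, keep, drop = FALSE],
               barcodes = rownames(x), genes = colnames(x)[keep])
}

#' Log-transform and standardize a count matrix
#'
#' Applies `log(1 + x)` elementwise, then centers and scales to unit
#' variance along the requested axis using the sample (divide by n - 1)
#' standard deviation, the convention of `scale()`. Constant slices are
#' mapped to all-zero rather than NaN, keeping dimensions stable for
#' downstream models.
#'
#' @param x a [count_matrix()] or non-negative numeric matrix.
#' @param axis standardize `"columns"` (genes) or `"rows"` (cells).
#' @param log whether to apply the `log1p` transform first (default TRUE).
#' @return a numeric matrix of class `transformed_matrix` with attribute
#'   `transform_tag`.
#' @export
log_standardize <- function(x, axis = c("columns", "rows"), log = TRUE) {
  axis <- match.arg(axis)
  m <- unclass(as.matrix(x))
  if (any(m < 0)) dv_stop("log_standardize expects non-negative input",
                          "dv_validation_error")
  if (log) m <- log1p(m)
  out <- standardize_mat(m, axis)
  dimnames(out) <- dimnames(m)
  attr(out, "transform_tag") <- paste0(
    if (log) "log-scaled+" else "",
    if (axis == "columns") "column-standardized" else "row-standardized")
  class(out) <- c("transformed_matrix", "matrix", "array")
  out
}
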