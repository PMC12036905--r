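# Expression-matrix container and on-disk formats.
#
# The package-wide convention is cells x genes: rows are cells, columns are
# genes.  The container is a plain base-R numeric matrix with rownames (cell
# ids) and colnames (gene ids), validated by expression_matrix(); dense
# algebra is intentional because the method builds an m x m self-expression
# matrix, so m is assumed modest (up to ~10^4 cells).

#' Construct a validated expression matrix
#'
#' @param values Numeric matrix, cells in rows, genes in columns. Entries
#'   must be non-negative and finite.
#' @param cell_ids,gene_ids Optional character vectors overriding the
#'   dimnames of `values`.  Cell ids must be unique.
#' @return The matrix with dimnames set, invisibly classed as a plain
#'   matrix (no S4 wrapper; all downstream functions take base matrices).
#' @export
#' @examples
#' x <- expression_matrix(matrix(1:6, 2, 3))
#' dim(x)
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative; found ",
         sum(values < 0), " negative entries", call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "),
         call. = FALSE)
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_ids))
  values
}

#' Read an expression matrix from disk
#'
#' Dense CSV/TSV files are expected cells x genes with a header row of gene
#' ids and a first column of cell ids.  Matrix Market (`.mtx`) input is
#' assumed genes x cells (the 10x convention) and transposed on read unless
#' `genes_as_rows = FALSE`; row/column names come from sidecar files
#' (`genes.tsv` and `barcodes.tsv` next to the `.mtx` by default).
#'
#' @param path Path to the matrix file.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"mtx"`.  `"auto"`
#'   dispatches on the file extension.
#' @param genes_as_rows For MTX input, whether rows of the sparse matrix
#'   are genes (default `TRUE`).
#' @param gene_file,cell_file Optional explicit sidecar paths for MTX
#'   input (first column of each file is used).
#' @return A cells x genes matrix as produced by [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                            genes_as_rows = TRUE,
                            gene_file = NULL, cell_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format=", call. = FALSE))
  }
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, comment.char = "")
    values <- as.matrix(df)
    storage.mode(values) <- "double"
    expression_matrix(values)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    read_ids <- function(f, n, prefix) {
      if (!is.null(f) && file.exists(f)) {
        ids <- utils::read.table(f, header = FALSE, sep = "\t",
                                 stringsAsFactors = FALSE)[[1]]
        if (length(ids) != n)
          stop("sidecar ", f, " has ", length(ids), " ids, expected ", n,
               call. = FALSE)
        as.character(ids)
      } else paste0(prefix, seq_len(n))
    }
    if (genes_as_rows) m <- t(m)
    if (is.null(gene_file)) gene_file <- file.path(dir, "genes.tsv")
    if (is.null(cell_file)) cell_file <- file.path(dir, "barcodes.tsv")
    expression_matrix(m,
                      cell_ids = read_ids(cell_file, nrow(m), "cell_"),
                      gene_ids = read_ids(gene_file, ncol(m), "gene_"))
  }
}

#' Construct a partition (cluster label vector)
#'
#' Labels are normalized to consecutive integer codes `0 .. k-1` in order
#' of the sorted unique input labels; the original labels are kept as
#' names-free attribute for reference.
#'
#' @param labels Vector of cluster assignments (integer, character or
#'   factor), one per cell.
#' @return Integer vector of codes in `[0, k)` with attribute `k`, classed
#'   `"partition"`.
#' @export
#' @examples
#' partition(c("b", "a", "b"))
partition <- function(labels) {
  if (inherits(labels, "partition")) return(labels)
  if (length(labels) == 0) {
    out <- integer(0)
  } else {
    if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
    lev <- sort(unique(labels))
    out <- match(labels, lev) - 1L
  }
  structure(out, k = length(unique(out)), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition of", length(x), "cells into", attr(x, "k"), "clusters\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Write cluster labels to a two-column CSV
#'
#' @param labels A [partition()] or plain label vector.
#' @param cell_ids Character vector of cell ids, same length as `labels`.
#' @param path Output path; columns are `cell_id,cluster`.
#' @export
write_labels <- function(labels, cell_ids, path) {
  labels <- partition(labels)
  if (length(labels) != length(cell_ids))
    stop("length mismatch: ", length(labels), " labels vs ",
         length(cell_ids), " cell ids", call. = FALSE)
  df <- data.frame(cell_id = as.character(cell_ids),
                   cluster = as.integer(labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cluster labels written by [write_labels()]
#'
#' @param path CSV with columns `cell_id,cluster`.
#' @return Named list with `labels` (a [partition()]) and `cell_ids`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cluster") %in% names(df)))
    stop("label file must have columns cell_id,cluster", call. = FALSE)
  list(labels = partition(df$cluster), cell_ids = as.character(df$cell_id))
}
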