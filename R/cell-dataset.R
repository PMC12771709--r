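#' Single-cell count dataset
#'
#' A lightweight container pairing a sparse gene-by-cell count matrix with
#' per-cell and per-gene annotation tibbles. Mitochondrial genes are
#' recognised by the human nomenclature prefix `MT-` and flagged
#' automatically; a normalized expression layer can be attached by
#' [normalize_counts()].
#'
#' @param counts A genes x cells matrix (dense or sparse; coerced to
#'   `dgCMatrix`) with gene symbols as rownames and cell barcodes as colnames.
#' @param cell_data A data frame with one row per cell. Must contain a
#'   `barcode` column matching `colnames(counts)`; typically also carries
#'   `condition`, `sample`, `cluster` and `cell_type`.
#' @param gene_data Optional data frame with one row per gene (`gene` column
#'   matching `rownames(counts)`). A logical `mito` column is added from the
#'   `MT-` prefix when absent; a logical `developmental` column defaults to
#'   `FALSE`.
#' @param study Optional study label (e.g. `"AD-like"`).
#'
#' @return An object of class `cell_dataset`: a list with elements `counts`
#'   (dgCMatrix), `normalized` (dgCMatrix or `NULL`), `cells` (tibble),
#'   `genes` (tibble) and `study`.
#' @export
#' @examples
#' m <- matrix(rpois(20, 2), nrow = 4,
#'             dimnames = list(c("A", "B", "MT-ND2", "D"), paste0("c", 1:5)))
#' cd <- cell_dataset(m, data.frame(barcode = paste0("c", 1:5),
#'                                  condition = c("ctrl", "ctrl", "dis", "dis", "dis")))
#' cd
cell_dataset <- function(counts, cell_data, gene_data = NULL, study = NULL) {
  if (!methods::is(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene symbols as rownames and cell barcodes as colnames.")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    abort("`counts` must contain non-negative integers.")
  }
  cells <- as_tibble(cell_data)
  if (!"barcode" %in% names(cells)) abort("`cell_data` must have a `barcode` column.")
  if (!identical(as.character(cells$barcode), colnames(counts))) {
    cells <- cells[match(colnames(counts), cells$barcode), , drop = FALSE]
    if (anyNA(cells$barcode)) abort("`cell_data$barcode` does not cover all columns of `counts`.")
  }
  genes <- if (is.null(gene_data)) tibble(gene = rownames(counts)) else as_tibble(gene_data)
  if (!"gene" %in% names(genes)) abort("`gene_data` must have a `gene` column.")
  genes <- genes[match(rownames(counts), genes$gene), , drop = FALSE]
  if (anyNA(genes$gene)) abort("`gene_data$gene` does not cover all rows of `counts`.")
  if (!"mito" %in% names(genes)) genes$mito <- startsWith(genes$gene, "MT-")
  if (!"developmental" %in% names(genes)) genes$developmental <- FALSE
  structure(
    list(counts = counts, normalized = NULL, cells = cells, genes = genes,
         study = study),
    class = "cell_dataset"
  )
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("<cell_dataset> %d genes x %d cells%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$study)) "" else paste0(" [", x$study, "]")))
  cat(sprintf("  mito genes: %d; normalized layer: %s\n",
              sum(x$genes$mito), if (is.null(x$normalized)) "absent" else "present"))
  extra <- setdiff(names(x$cells), "barcode")
  if (length(extra)) cat("  cell annotations:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

#' Number of cells / genes in a dataset
#' @param data A [cell_dataset()].
#' @return Integer count.
#' @export
n_cells <- function(data) ncol(data$counts)

#' @rdname n_cells
#' @export
n_genes <- function(data) nrow(data$counts)

#' Per-cell quality-control metrics
#'
#' Computes, on raw counts, the number of detected genes (count > 0), the
#' total UMI count, and the mitochondrial percentage
#' `100 * sum(MT- gene counts) / total`.
#'
#' @param data A [cell_dataset()].
#' @return A tibble with columns `barcode`, `n_detected`, `total_counts`,
#'   `mito_pct`.
#' @export
per_cell_qc <- function(data) {
  stopifnot(is(data, "cell_dataset"))
  total <- Matrix::colSums(data$counts)
  detected <- Matrix::colSums(data$counts > 0)
  mito <- Matrix::colSums(data$counts[data$genes$mito, , drop = FALSE])
  tibble(
    barcode = colnames(data$counts),
    n_detected = as.integer(unname(detected)),
    total_counts = as.numeric(unname(total)),
    mito_pct = unname(ifelse(total > 0, 100 * mito / total, 0))
  )
}

#' Read a dataset from a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx` (1-based MatrixMarket coordinates, genes x cells),
#' `features.tsv` (gene symbols, first column), `barcodes.tsv` (one barcode
#' per line) and optionally `cells.tsv` (tab-separated per-cell annotations
#' with a `barcode` column).
#'
#' @param dir Directory containing the triplet files.
#' @param study Optional study label.
#' @return A [cell_dataset()].
#' @export
read_cell_dataset <- function(dir, study = NULL) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) abort(paste0("No matrix.mtx under ", dir))
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feats <- readr::read_tsv(file.path(dir, "features.tsv"),
                           col_names = FALSE, show_col_types = FALSE)
  bcs <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                         col_names = FALSE, show_col_types = FALSE)
  rownames(m) <- feats[[1]]
  colnames(m) <- bcs[[1]]
  ann_path <- file.path(dir, "cells.tsv")
  cells <- if (file.exists(ann_path)) {
    readr::read_tsv(ann_path, show_col_types = FALSE)
  } else {
    tibble(barcode = colnames(m))
  }
  cell_dataset(m, cells, study = study)
}

#' Write a dataset as a 10x-style MatrixMarket triplet directory
#'
#' @param data A [cell_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_dataset <- function(data, dir) {
  stopifnot(is(data, "cell_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(data$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(gene = rownames(data$counts)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(barcode = colnames(data$counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(data$cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a dense TSV count matrix as a dataset
#'
#' First column is the gene symbol; remaining columns are cells named by
#' barcode.
#'
#' @param path TSV file path.
#' @param cell_data Optional per-cell annotation data frame.
#' @param study Optional study label.
#' @return A [cell_dataset()].
#' @export
read_dense_counts <- function(path, cell_data = NULL, study = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  if (is.null(cell_data)) cell_data <- tibble(barcode = colnames(m))
  cell_dataset(m, cell_data, study = study)
}

# subset a cell_dataset by cell index/logical, keeping layers in step
subset_cells <- function(data, idx) {
  data$counts <- data$counts[, idx, drop = FALSE]
  if (!is.null(data$normalized)) data$normalized <- data$normalized[, idx, drop = FALSE]
  data$cells <- data$cells[idx, , drop = FALSE]
  data
}
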