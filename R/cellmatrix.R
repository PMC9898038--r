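#' Construct a single-cell count container
#'
#' The universal container for gene-by-cell counts plus per-cell metadata.
#' Counts are stored as a sparse `dgCMatrix` with genes in rows and cells in
#' columns; metadata is a tibble with one row per cell.
#'
#' @param counts sparse (or dense) nonnegative integer matrix, genes x cells,
#'   with row and column names.
#' @param cell_meta data frame with columns `cell_id`, `sample`,
#'   `condition` (one of `"HC"`, `"AML"`), `patient` and optionally
#'   `timepoint`; rows must match `colnames(counts)`.
#' @return an object of class `cell_matrix`: a list with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
cell_matrix <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_ls("counts must carry gene (row) and cell (column) names")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    abort_ls("counts must be nonnegative integers")
  }
  cell_meta <- tibble::as_tibble(cell_meta)
  need <- c("cell_id", "sample", "condition", "patient")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss)) abort_ls("cell_meta missing columns: ", paste(miss, collapse = ", "))
  if (!all(cell_meta$condition %in% c("HC", "AML"))) {
    abort_ls("condition must be 'HC' or 'AML'")
  }
  if (!identical(as.character(cell_meta$cell_id), colnames(counts))) {
    abort_ls("cell_meta rows must match counts columns (same cells, same order)")
  }
  structure(
    list(counts = counts, gene_ids = rownames(counts),
         cell_ids = colnames(counts), cell_meta = cell_meta),
    class = "cell_matrix"
  )
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("<cell_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells; ",
      length(unique(x$cell_meta$sample)), " samples (",
      sum(x$cell_meta$condition == "AML"), " AML cells / ",
      sum(x$cell_meta$condition == "HC"), " HC cells)\n", sep = "")
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Write a cell matrix as a MatrixMarket trio
#'
#' Writes `matrix.mtx` (genes x cells counts), `features.tsv` (gene ids) and
#' `metadata.tsv` (cell metadata, first column `cell_id`) into `dir`.
#'
#' @param m a [cell_matrix()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cellmatrix <- function(m, dir) {
  stopifnot(inherits(m, "cell_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(dir, "features.tsv"))
  readr::write_tsv(m$cell_meta, file.path(dir, "metadata.tsv"))
  invisible(dir)
}

#' Read a cell matrix from a MatrixMarket trio
#'
#' Inverse of [write_cellmatrix()]; the round trip is lossless for counts
#' and metadata.
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `metadata.tsv`.
#' @return a [cell_matrix()].
#' @export
read_cellmatrix <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "metadata.tsv"))
  for (p in paths) if (!file.exists(p)) abort_ls("missing file: ", p)
  counts <- tryCatch(Matrix::readMM(paths[1]),
                     error = function(e) abort_ls("failed to parse ", paths[1], ": ", conditionMessage(e)))
  # writeMM stores symmetric patterns in a dimname-sharing class; force general
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  genes <- readLines(paths[2])
  meta <- readr::read_tsv(paths[3], show_col_types = FALSE)
  if (nrow(counts) != length(genes)) {
    abort_ls("dimension mismatch: matrix.mtx has ", nrow(counts),
             " rows but features.tsv has ", length(genes), " lines")
  }
  if (ncol(counts) != nrow(meta)) {
    abort_ls("dimension mismatch: matrix.mtx has ", ncol(counts),
             " columns but metadata.tsv has ", nrow(meta), " rows")
  }
  rownames(counts) <- genes
  colnames(counts) <- as.character(meta$cell_id)
  cell_matrix(counts, meta)
}
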