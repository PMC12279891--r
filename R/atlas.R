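#' Single-cell atlas container
#'
#' A `cell_atlas` holds a sparse genes x cells raw count matrix together
#' with per-cell metadata: `cell_id`, `cell_type`, `sample_id`,
#' `tissue_group` and optionally `grade`. Per-cell statistics are computed
#' over the matrix columns.
#'
#' @param counts Non-negative integer matrix, genes in rows, cells in
#'   columns. Coerced to a sparse `dgCMatrix`.
#' @param meta data.frame with one row per cell; must contain `cell_id`,
#'   `cell_type`, `sample_id`, `tissue_group` (optionally `grade`), in the
#'   same order as the matrix columns.
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   the matrix rownames or `gene1..geneN`.
#'
#' @return A validated `cell_atlas` object.
#' @export
cell_atlas <- function(counts, meta, gene_ids = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  required <- c("cell_id", "cell_type", "sample_id", "tissue_group")
  missing_cols <- setdiff(required, colnames(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (ncol(counts) != nrow(meta)) {
    stop(sprintf(
      "dimension mismatch: counts has %d cells (columns) but metadata has %d rows",
      ncol(counts), nrow(meta)), call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- rownames(counts)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  }
  if (length(gene_ids) != nrow(counts)) {
    stop(sprintf("gene_ids has length %d but counts has %d genes (rows)",
                 length(gene_ids), nrow(counts)), call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids", call. = FALSE)
  if (anyDuplicated(meta$cell_id)) stop("duplicate cell_ids", call. = FALSE)
  if (any(counts@x < 0)) stop("counts has negative entries", call. = FALSE)
  if (anyNA(meta[required])) {
    stop("metadata has missing values in a required column", call. = FALSE)
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- meta$cell_id
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  rownames(meta) <- meta$cell_id
  structure(list(counts = counts, meta = meta, gene_ids = gene_ids),
            class = "cell_atlas")
}

#' @export
print.cell_atlas <- function(x, ...) {
  cat(sprintf("cell_atlas: %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  cell types: %s\n",
              paste(sort(unique(x$meta$cell_type)), collapse = ", ")))
  cat(sprintf("  samples: %d, tissue groups: %s\n",
              length(unique(x$meta$sample_id)),
              paste(sort(unique(x$meta$tissue_group)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.cell_atlas <- function(x) dim(x$counts)

#' Subset an atlas to a set of cells
#'
#' @param atlas A `cell_atlas`.
#' @param keep Logical or integer index over cells.
#' @return The restricted `cell_atlas`.
#' @export
subset_cells <- function(atlas, keep) {
  stopifnot(inherits(atlas, "cell_atlas"))
  cell_atlas(atlas$counts[, keep, drop = FALSE],
             atlas$meta[keep, , drop = FALSE],
             gene_ids = atlas$gene_ids)
}

#' Read a single-cell atlas from Matrix Market counts plus TSV metadata
#'
#' @param matrix_path Path to a Matrix Market (.mtx) coordinate file,
#'   genes x cells.
#' @param metadata_path Path to a TSV with one row per cell and columns
#'   `cell_id`, `cell_type`, `sample_id`, `tissue_group` (optional `grade`),
#'   ordered as the matrix columns.
#' @param genes_path Optional path to a one-column text file of gene ids
#'   (one per matrix row); when absent genes are named `gene1..geneN`.
#'
#' @return A `cell_atlas`.
#' @export
read_atlas <- function(matrix_path, metadata_path, genes_path = NULL) {
  counts <- Matrix::readMM(matrix_path)
  meta <- utils::read.delim(metadata_path, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  gene_ids <- NULL
  if (!is.null(genes_path)) {
    gene_ids <- readLines(genes_path)
    gene_ids <- gene_ids[nzchar(gene_ids)]
  }
  cell_atlas(counts, meta, gene_ids = gene_ids)
}

#' Write a single-cell atlas as Matrix Market counts plus TSV metadata
#'
#' @param atlas A `cell_atlas`.
#' @param dir Output directory (created if needed); writes `counts.mtx`,
#'   `cells.tsv` and `genes.txt`.
#' @return Invisibly, the paths written.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "cell_atlas"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mtx <- file.path(dir, "counts.mtx")
  tsv <- file.path(dir, "cells.tsv")
  genes <- file.path(dir, "genes.txt")
  Matrix::writeMM(atlas$counts, mtx)
  utils::write.table(atlas$meta, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(atlas$gene_ids, genes)
  invisible(c(matrix = mtx, metadata = tsv, genes = genes))
}

#' Filter cells on detected genes and total counts
#'
#' Keeps cells with at least `qc_min_genes_cell` detected genes and at least
#' `qc_min_counts_cell` total raw counts (cells below either threshold are
#' excluded, matching a strict "fewer than" exclusion rule). Idempotent.
#'
#' @param atlas A `cell_atlas`.
#' @param cfg A [pipeline_config()].
#' @return The filtered `cell_atlas`.
#' @export
qc_filter_cells <- function(atlas, cfg = pipeline_config()) {
  stopifnot(inherits(atlas, "cell_atlas"))
  detected <- Matrix::colSums(atlas$counts > 0)
  total <- Matrix::colSums(atlas$counts)
  keep <- detected >= cfg$qc_min_genes_cell & total >= cfg$qc_min_counts_cell
  if (!any(keep)) stop("no cells pass QC", call. = FALSE)
  message(sprintf("qc_filter_cells: %d of %d cells retained (%d removed)",
                  sum(keep), length(keep), sum(!keep)))
  subset_cells(atlas, keep)
}
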