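#' Spatial bead abundance container
#'
#' Holds bead coordinates and a beads x cell-types abundance matrix — the
#' downstream surrogate for a deconvolution posterior weight matrix (e.g. a
#' Q05 abundance matrix) — plus per-bead UMI and detected-gene counts used
#' for QC and the bead's source tissue group. Coordinates are unitless
#' Euclidean.
#'
#' @param coords Numeric matrix/data.frame with columns `x`, `y`, one row
#'   per bead.
#' @param abundance Non-negative numeric matrix, beads x cell types, with
#'   cell-type column names.
#' @param bead_umi Optional non-negative integer per bead (needed for QC).
#' @param bead_genes Optional non-negative integer per bead (needed for QC).
#' @param tissue_group Optional tissue-group label per bead (or scalar).
#' @param bead_ids Unique bead identifiers; default `bead1..beadN`.
#'
#' @return A `spatial_map` object.
#' @export
spatial_map <- function(coords, abundance, bead_umi = NULL, bead_genes = NULL,
                        tissue_group = NULL, bead_ids = NULL) {
  coords <- as.matrix(coords[, c("x", "y")])
  storage.mode(coords) <- "double"
  abundance <- as.matrix(abundance)
  n <- nrow(coords)
  if (nrow(abundance) != n) {
    stop(sprintf("coords has %d beads but abundance has %d rows",
                 n, nrow(abundance)), call. = FALSE)
  }
  if (any(abundance < 0)) stop("abundance has negative entries", call. = FALSE)
  if (any(!is.finite(coords))) stop("coords must be finite", call. = FALSE)
  if (is.null(colnames(abundance))) {
    colnames(abundance) <- paste0("type", seq_len(ncol(abundance)))
  }
  if (is.null(bead_ids)) bead_ids <- paste0("bead", seq_len(n))
  if (anyDuplicated(bead_ids)) stop("duplicate bead ids", call. = FALSE)
  if (!is.null(tissue_group) && length(tissue_group) == 1L) {
    tissue_group <- rep(tissue_group, n)
  }
  rownames(coords) <- rownames(abundance) <- bead_ids
  structure(list(coords = coords, abundance = abundance,
                 bead_umi = bead_umi, bead_genes = bead_genes,
                 tissue_group = tissue_group, bead_ids = bead_ids),
            class = "spatial_map")
}

#' @export
print.spatial_map <- function(x, ...) {
  cat(sprintf("spatial_map: %d beads x %d cell types\n",
              nrow(x$abundance), ncol(x$abundance)))
  invisible(x)
}

#' Read a spatial map from coordinate and abundance tables
#'
#' @param coords_path TSV with columns `bead_id`, `x`, `y` and optionally
#'   `bead_umi`, `bead_genes`, `tissue_group`.
#' @param abundance_path TSV with a `bead_id` column followed by one column
#'   per cell type; rows matched to `coords_path` by `bead_id`.
#' @return A `spatial_map`.
#' @export
read_spatial <- function(coords_path, abundance_path) {
  co <- utils::read.delim(coords_path, sep = "\t", stringsAsFactors = FALSE)
  ab <- utils::read.delim(abundance_path, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("bead_id", "x", "y")) {
    if (!col %in% colnames(co)) {
      stop("coords table is missing required column: ", col, call. = FALSE)
    }
  }
  if (!"bead_id" %in% colnames(ab)) {
    stop("abundance table is missing required column: bead_id", call. = FALSE)
  }
  idx <- match(co$bead_id, ab$bead_id)
  if (anyNA(idx)) stop("abundance table is missing beads present in coords",
                       call. = FALSE)
  abm <- as.matrix(ab[idx, setdiff(colnames(ab), "bead_id"), drop = FALSE])
  spatial_map(coords = data.frame(x = co$x, y = co$y),
              abundance = abm,
              bead_umi = co$bead_umi, bead_genes = co$bead_genes,
              tissue_group = co$tissue_group, bead_ids = co$bead_id)
}

#' Write a spatial map as coordinate and abundance TSVs
#'
#' @param spatial A `spatial_map`.
#' @param dir Output directory; writes `beads.tsv` and `abundance.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_spatial <- function(spatial, dir) {
  stopifnot(inherits(spatial, "spatial_map"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  co <- data.frame(bead_id = spatial$bead_ids,
                   x = spatial$coords[, "x"], y = spatial$coords[, "y"])
  if (!is.null(spatial$bead_umi)) co$bead_umi <- spatial$bead_umi
  if (!is.null(spatial$bead_genes)) co$bead_genes <- spatial$bead_genes
  if (!is.null(spatial$tissue_group)) co$tissue_group <- spatial$tissue_group
  ab <- data.frame(bead_id = spatial$bead_ids, spatial$abundance,
                   check.names = FALSE)
  beads <- file.path(dir, "beads.tsv")
  abund <- file.path(dir, "abundance.tsv")
  utils::write.table(co, beads, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ab, abund, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(coords = beads, abundance = abund))
}

subset_beads <- function(spatial, keep) {
  spatial_map(coords = data.frame(x = spatial$coords[keep, "x"],
                                  y = spatial$coords[keep, "y"]),
              abundance = spatial$abundance[keep, , drop = FALSE],
              bead_umi = spatial$bead_umi[keep],
              bead_genes = spatial$bead_genes[keep],
              tissue_group = spatial$tissue_group[keep],
              bead_ids = spatial$bead_ids[keep])
}

#' Filter beads on UMI and detected-gene thresholds
#'
#' Keeps beads with at least `qc_min_umi_bead` UMIs and at least
#' `qc_min_genes_bead` detected genes (beads below either threshold are
#' excluded). Coordinates and abundance are subset consistently.
#'
#' @param spatial A `spatial_map` with `bead_umi` and `bead_genes` present.
#' @param cfg A [pipeline_config()].
#' @return The filtered `spatial_map`.
#' @export
qc_filter_beads <- function(spatial, cfg = pipeline_config()) {
  stopifnot(inherits(spatial, "spatial_map"))
  if (is.null(spatial$bead_umi) || is.null(spatial$bead_genes)) {
    stop("bead_umi and bead_genes are required for bead QC", call. = FALSE)
  }
  keep <- spatial$bead_umi >= cfg$qc_min_umi_bead &
    spatial$bead_genes >= cfg$qc_min_genes_bead
  if (!any(keep)) stop("no beads pass QC", call. = FALSE)
  message(sprintf("qc_filter_beads: %d of %d beads retained (%d removed)",
                  sum(keep), length(keep), sum(!keep)))
  subset_beads(spatial, keep)
}
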