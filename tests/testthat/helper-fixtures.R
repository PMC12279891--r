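# Small in-code fixtures shared across test files.

# A minimal labelled atlas from an explicit dense count matrix.
make_toy_atlas <- function(counts, cell_type, sample_id = "s1",
                           tissue_group = "tumor") {
  n <- ncol(counts)
  ids <- colnames(counts)
  if (is.null(ids)) ids <- paste0("c", seq_len(n))
  cell_atlas(counts, data.frame(
    cell_id = ids,
    cell_type = rep_len(cell_type, n),
    sample_id = rep_len(sample_id, n),
    tissue_group = rep_len(tissue_group, n),
    stringsAsFactors = FALSE))
}

# Cells straddling every QC threshold: detected genes 399/400 and total
# counts 799/800 in all four combinations.
make_qc_edge_atlas <- function() {
  n_genes <- 450
  build_cell <- function(detected, total) {
    x <- integer(n_genes)
    x[seq_len(detected)] <- 1L
    x[1] <- x[1] + (total - detected)
    x
  }
  counts <- cbind(
    pass_both = build_cell(400, 800),
    low_genes = build_cell(399, 1000),
    low_counts = build_cell(400, 799),
    low_both = build_cell(399, 799),
    high_both = build_cell(420, 5000))
  make_toy_atlas(counts, "T")
}

# Beads straddling the UMI (499/500) and detected-gene (199/200) cuts.
make_qc_edge_beads <- function() {
  spatial_map(
    coords = data.frame(x = 1:5, y = rep(0, 5)),
    abundance = matrix(0.5, 5, 2, dimnames = list(NULL, c("A", "B"))),
    bead_umi = c(500L, 499L, 500L, 10000L, 499L),
    bead_genes = c(200L, 300L, 199L, 199L, 199L),
    bead_ids = c("keep", "low_umi", "low_genes", "high_umi_low_genes",
                 "low_both"))
}

# Three collinear beads used by the worked KNN examples.
make_collinear_beads <- function() {
  spatial_map(coords = data.frame(x = c(0, 1, 2), y = c(0, 0, 0)),
              abundance = matrix(c(1, 0, 1,
                                   0, 1, 1), ncol = 2,
                                 dimnames = list(NULL, c("A", "B"))))
}
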