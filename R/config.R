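#' Pipeline configuration
#'
#' Bundles the quality-control thresholds and analysis defaults used across
#' the pipeline. Cells are kept when they show at least `qc_min_genes_cell`
#' detected genes *and* at least `qc_min_counts_cell` total counts; beads are
#' kept when they carry at least `qc_min_umi_bead` UMIs *and*
#' `qc_min_genes_bead` detected genes. The defaults mirror the strict
#' "fewer than" exclusion rules of the source study, so the keep-condition
#' is `>=` the threshold.
#'
#' @param qc_min_genes_cell Minimum detected genes per cell (default 400).
#' @param qc_min_counts_cell Minimum total raw counts per cell (default 800).
#' @param qc_min_umi_bead Minimum UMIs per bead (default 500).
#' @param qc_min_genes_bead Minimum detected genes per bead (default 200).
#' @param k_community Number of nearest beads forming a cell community
#'   (default 20).
#' @param fdr_alpha FDR threshold for enrichment calls (default 0.05).
#' @param deg_p Raw p-value cut for selecting DEGs (default 0.05).
#' @param rng_seed Integer seed for seeded steps (default 0).
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(qc_min_genes_cell = 400L,
                            qc_min_counts_cell = 800L,
                            qc_min_umi_bead = 500L,
                            qc_min_genes_bead = 200L,
                            k_community = 20L,
                            fdr_alpha = 0.05,
                            deg_p = 0.05,
                            rng_seed = 0L) {
  cfg <- list(
    qc_min_genes_cell = as.integer(qc_min_genes_cell),
    qc_min_counts_cell = as.integer(qc_min_counts_cell),
    qc_min_umi_bead = as.integer(qc_min_umi_bead),
    qc_min_genes_bead = as.integer(qc_min_genes_bead),
    k_community = as.integer(k_community),
    fdr_alpha = fdr_alpha,
    deg_p = deg_p,
    rng_seed = as.integer(rng_seed)
  )
  thresholds <- c(cfg$qc_min_genes_cell, cfg$qc_min_counts_cell,
                  cfg$qc_min_umi_bead, cfg$qc_min_genes_bead,
                  cfg$k_community)
  if (any(thresholds[1:4] <= 0L)) {
    stop("all QC thresholds must be strictly positive", call. = FALSE)
  }
  if (cfg$k_community < 0L) stop("k_community must be >= 0", call. = FALSE)
  for (p in c("fdr_alpha", "deg_p")) {
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1) {
      stop(sprintf("%s must lie in (0, 1)", p), call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}
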