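#' Per-sample pseudobulk for one cell type
#'
#' Sums raw counts over all cells of `cell_type` within each sample,
#' yielding a samples x genes matrix suited to sample-level differential
#' expression. Samples contributing fewer than `min_cells` cells of the
#' type are dropped with a warning.
#'
#' @param atlas A `cell_atlas`.
#' @param cell_type Cell type to aggregate.
#' @param min_cells Minimum cells per sample (default 10).
#' @return A `pseudobulk` object: list with `counts` (samples x genes),
#'   `n_cells` per sample, `group` (tissue group per sample).
#' @export
build_pseudobulk <- function(atlas, cell_type, min_cells = 10L) {
  stopifnot(inherits(atlas, "cell_atlas"))
  sel <- atlas$meta$cell_type == cell_type
  if (!any(sel)) stop("cell type not present in atlas: ", cell_type,
                      call. = FALSE)
  meta <- atlas$meta[sel, , drop = FALSE]
  counts <- atlas$counts[, sel, drop = FALSE]
  samples <- unique(meta$sample_id)
  n_cells <- vapply(samples, function(s) sum(meta$sample_id == s), integer(1))
  drop <- n_cells < min_cells
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) with < %d %s cells: %s",
                    sum(drop), min_cells, cell_type,
                    paste(samples[drop], collapse = ", ")))
  }
  samples <- samples[!drop]
  if (length(samples) == 0) {
    stop("no sample retains >= ", min_cells, " cells of type ", cell_type,
         call. = FALSE)
  }
  pb <- t(vapply(samples, function(s) {
    Matrix::rowSums(counts[, meta$sample_id == s, drop = FALSE])
  }, numeric(nrow(counts))))
  rownames(pb) <- samples
  colnames(pb) <- atlas$gene_ids
  group <- vapply(samples, function(s) {
    as.character(meta$tissue_group[meta$sample_id == s][1])
  }, character(1))
  structure(list(counts = pb, n_cells = n_cells[!drop], group = group,
                 cell_type = cell_type),
            class = "pseudobulk")
}

#' Log2 counts-per-million normalization
#'
#' @param pb A `pseudobulk` or a samples x genes count matrix.
#' @return Matrix of `log2(CPM + 1)` values, samples x genes.
#' @export
normalize_cpm <- function(pb) {
  counts <- if (inherits(pb, "pseudobulk")) pb$counts else as.matrix(pb)
  lib <- rowSums(counts)
  if (any(lib == 0)) {
    stop("zero library size for sample(s): ",
         paste(rownames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  }
  log2(counts / lib * 1e6 + 1)
}

# Vectorized Welch two-sample t-test across matrix columns.
# Zero pooled standard error (both groups constant) yields t = 0, p = 1.
welch_t_columns <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1))),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
  list(t = tstat, df = df, p = p, mean_a = ma, mean_b = mb)
}

#' Pseudobulk differential expression (Welch t on log2 CPM)
#'
#' Per gene, Welch's two-sample t-test on `log2(CPM + 1)` between two
#' tissue groups; the log2 fold-change is `mean(group_a) - mean(group_b)`
#' on that scale. Genes with zero variance in both groups get `p = 1`.
#' Genes with `p < deg_p` are flagged `selected`.
#'
#' @param pb A `pseudobulk`.
#' @param group_a,group_b Tissue-group labels to contrast (a minus b).
#' @param deg_p Raw p-value cut for DEG selection (default 0.05).
#' @return A data.frame (`deg_table`) with `gene`, `log2fc`, `t`, `p`,
#'   `selected`.
#' @export
differential_expression <- function(pb, group_a, group_b, deg_p = 0.05) {
  stopifnot(inherits(pb, "pseudobulk"))
  in_a <- pb$group == group_a
  in_b <- pb$group == group_b
  if (sum(in_a) < 2 || sum(in_b) < 2) {
    stop(sprintf("need >= 2 samples per group, got %d (%s) and %d (%s)",
                 sum(in_a), group_a, sum(in_b), group_b), call. = FALSE)
  }
  norm <- normalize_cpm(pb)
  wt <- welch_t_columns(norm[in_a, , drop = FALSE], norm[in_b, , drop = FALSE])
  out <- data.frame(gene = colnames(norm),
                    log2fc = wt$mean_a - wt$mean_b,
                    t = wt$t, p = wt$p,
                    selected = wt$p < deg_p,
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  attr(out, "deg_p") <- deg_p
  out
}

#' Cytokine-signature dictionary
#'
#' @param signatures Numeric matrix, cytokines x genes, of per-cytokine
#'   response signatures (e.g. log2 fold-changes of cytokine-induced
#'   programs).
#' @param cytokine_names,gene_ids Unique row/column names; default to the
#'   matrix dimnames.
#' @return A `cytokine_dictionary`.
#' @export
cytokine_dictionary <- function(signatures, cytokine_names = NULL,
                                gene_ids = NULL) {
  signatures <- as.matrix(signatures)
  if (is.null(cytokine_names)) cytokine_names <- rownames(signatures)
  if (is.null(gene_ids)) gene_ids <- colnames(signatures)
  if (is.null(cytokine_names) || is.null(gene_ids)) {
    stop("cytokine names and gene ids are required", call. = FALSE)
  }
  if (anyDuplicated(cytokine_names)) stop("duplicate cytokine names",
                                          call. = FALSE)
  rownames(signatures) <- cytokine_names
  colnames(signatures) <- gene_ids
  structure(list(signatures = signatures, cytokine_names = cytokine_names,
                 gene_ids = gene_ids),
            class = "cytokine_dictionary")
}

#' Read a cytokine dictionary from TSV
#'
#' @param path TSV whose first column is the cytokine name and remaining
#'   columns are per-gene signature values.
#' @return A `cytokine_dictionary`.
#' @export
read_cytokine_dictionary <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  cytokine_dictionary(as.matrix(df[, -1, drop = FALSE]),
                      cytokine_names = df[[1]],
                      gene_ids = colnames(df)[-1])
}

cosine_similarity <- function(v, s) {
  nv <- sqrt(sum(v^2)); ns <- sqrt(sum(s^2))
  if (nv == 0 || ns == 0) return(NA_real_)
  sum(v * s) / (nv * ns)
}

# Selected-DEG log2fc vector restricted to dictionary genes.
deg_dictionary_vector <- function(degs, dict) {
  sel <- degs[degs$selected, , drop = FALSE]
  genes <- intersect(sel$gene, dict$gene_ids)
  if (length(genes) == 0) stop("no DEGs in dictionary", call. = FALSE)
  stats::setNames(sel$log2fc[match(genes, sel$gene)], genes)
}

#' Cytokine response enrichment by cosine similarity
#'
#' Restricts the selected DEGs' signed log2 fold-changes to the genes of
#' the cytokine dictionary and scores each cytokine by the cosine
#' similarity between that vector and the cytokine's signature over the
#' same genes. Cytokines whose signature is all-zero on the overlap get
#' `NA` cosine.
#'
#' @param degs A `deg_table` from [differential_expression()].
#' @param dict A `cytokine_dictionary`.
#' @return A data.frame with `cytokine`, `cosine`, `n_genes_used`.
#' @export
irea_score <- function(degs, dict) {
  stopifnot(inherits(dict, "cytokine_dictionary"))
  v <- deg_dictionary_vector(degs, dict)
  S <- dict$signatures[, names(v), drop = FALSE]
  cosine <- apply(S, 1, function(s) cosine_similarity(v, s))
  data.frame(cytokine = dict$cytokine_names, cosine = unname(cosine),
             n_genes_used = length(v), stringsAsFactors = FALSE)
}

#' Cytokine response enrichment with permutation p-values and BH FDR
#'
#' The null distribution is built by permuting the gene labels of the DEG
#' vector (the signed log2 fold-changes are reassigned to the overlap
#' genes at random) and recomputing each cytokine's cosine; the one-sided
#' enrichment p-value is `(1 + #{null >= observed}) / (n_perm + 1)` and
#' Benjamini-Hochberg adjustment across cytokines gives `q`.
#'
#' @param degs A `deg_table`.
#' @param dict A `cytokine_dictionary`.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Seed for the permutations.
#' @return A data.frame with `cytokine`, `cosine`, `perm_p`, `q`,
#'   `n_genes_used`, sorted as the dictionary.
#' @export
irea_permutation_fdr <- function(degs, dict, n_perm = 1000L, seed = 0L) {
  stopifnot(inherits(dict, "cytokine_dictionary"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  v <- deg_dictionary_vector(degs, dict)
  m <- length(v)
  S <- dict$signatures[, names(v), drop = FALSE]
  s_norm <- sqrt(rowSums(S^2))
  v_norm <- sqrt(sum(v^2))
  obs <- as.vector(S %*% v) / (s_norm * v_norm)
  obs[s_norm == 0] <- NA_real_
  set.seed(seed)
  # permutations x genes matrix of relabelled DEG vectors
  P <- t(vapply(seq_len(n_perm), function(i) v[sample.int(m)], numeric(m)))
  null_cos <- P %*% t(S) / (v_norm * rep(1, n_perm) %o% s_norm)
  exceed <- colSums(sweep(null_cos, 2, obs, ">="))
  perm_p <- (1 + exceed) / (n_perm + 1)
  perm_p[is.na(obs)] <- NA_real_
  q <- rep(NA_real_, length(obs))
  ok <- !is.na(perm_p)
  q[ok] <- stats::p.adjust(perm_p[ok], method = "BH")
  data.frame(cytokine = dict$cytokine_names, cosine = obs,
             perm_p = perm_p, q = q, n_genes_used = m,
             stringsAsFactors = FALSE)
}

#' Sample-level pseudobulk gene-gene correlation
#'
#' Correlates the normalized pseudobulk expression of two genes across
#' samples (e.g. STAT5A against IL2RA in regulatory T cells).
#'
#' @param pb_norm Normalized samples x genes matrix from
#'   [normalize_cpm()].
#' @param gene_x,gene_y Gene ids to correlate.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p`, `n`, `method`; `r` is NA with
#'   `undefined = TRUE` when either gene has zero variance.
#' @export
pseudobulk_correlation <- function(pb_norm, gene_x, gene_y,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  for (g in c(gene_x, gene_y)) {
    if (!g %in% colnames(pb_norm)) {
      stop("gene not present in pseudobulk: ", g, call. = FALSE)
    }
  }
  x <- pb_norm[, gene_x]
  y <- pb_norm[, gene_y]
  n <- length(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, method = method,
                undefined = TRUE))
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ht$estimate), p = ht$p.value, n = n, method = method,
       undefined = FALSE)
}
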