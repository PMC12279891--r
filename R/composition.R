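#' Build a subtype x tissue composition table
#'
#' Cross-tabulates two metadata columns into the observed count matrix
#' `O[i, j]` with row totals `r`, column totals `c` and grand total `N` —
#' the input to the observed/expected tissue-preference analysis.
#'
#' @param atlas A `cell_atlas`.
#' @param row_key,col_key Metadata column names (e.g. `cell_type` and
#'   `tissue_group`).
#' @return A `composition_table` with elements `O`, `r`, `c`, `N`.
#' @export
tabulate_composition <- function(atlas, row_key = "cell_type",
                                 col_key = "tissue_group") {
  stopifnot(inherits(atlas, "cell_atlas"))
  if (nrow(atlas$meta) == 0) stop("atlas has no cells", call. = FALSE)
  for (key in c(row_key, col_key)) {
    if (!key %in% colnames(atlas$meta)) {
      stop("metadata has no column named: ", key, call. = FALSE)
    }
  }
  O <- unclass(table(atlas$meta[[row_key]], atlas$meta[[col_key]]))
  composition_table(O)
}

#' Construct a composition table from an observed count matrix
#'
#' @param O Non-negative integer matrix of observed counts (subtypes x
#'   tissues).
#' @return A `composition_table` with margins and grand total.
#' @export
composition_table <- function(O) {
  O <- as.matrix(O)
  if (any(O < 0)) stop("observed counts must be non-negative", call. = FALSE)
  structure(list(O = O, r = rowSums(O), c = colSums(O), N = sum(O)),
            class = "composition_table")
}

#' Observed/expected (Ro/e) tissue-preference ratio
#'
#' Under independence of subtype and tissue the expected count is
#' `E[i, j] = r[i] * c[j] / N`; the ratio `Ro/e[i, j] = O[i, j] / E[i, j]`
#' exceeds 1 where subtype i is enriched in tissue j and falls below 1
#' where it is depleted. Cells with `E = 0` are flagged undefined (NA)
#' rather than infinite.
#'
#' @param table A `composition_table`.
#' @return An `oe_result` with `E`, `ratio`, `undefined` (logical matrix).
#' @export
oe_ratio <- function(table) {
  stopifnot(inherits(table, "composition_table"))
  if (table$N <= 0) stop("composition table has N = 0", call. = FALSE)
  E <- outer(table$r, table$c) / table$N
  undefined <- E == 0
  ratio <- ifelse(undefined, NA_real_, table$O / E)
  dimnames(E) <- dimnames(ratio) <- dimnames(table$O)
  structure(list(O = table$O, E = E, ratio = ratio, undefined = undefined,
                 test_p = NULL, test_used = NULL),
            class = "oe_result")
}

#' @export
print.oe_result <- function(x, ...) {
  cat("oe_result: Ro/e ratios\n")
  print(round(x$ratio, 3))
  if (!is.null(x$test_p)) {
    cat(sprintf("table-wide %s p = %.4g\n", x$test_used, x$test_p))
  }
  invisible(x)
}

#' Significance of deviation from the expected composition
#'
#' Tests the table-wide null of independence. By default (`method =
#' "auto"`) a Pearson chi-square test without continuity correction is
#' used when every expected count is at least 5 (Cochran's rule), and
#' Fisher's exact test otherwise — exact for 2x2 tables, Monte Carlo
#' (fixed seed) for larger ones. When `per_cell = TRUE` each (subtype,
#' tissue) cell is additionally collapsed to a 2x2 table (cell vs rest)
#' and tested the same way, with BH adjustment across cells.
#'
#' @param table A `composition_table`.
#' @param method `"auto"`, `"chisq"` or `"fisher"`.
#' @param per_cell Also compute per-cell p-values (default FALSE).
#' @param seed Seed for the Monte Carlo Fisher p on tables larger than 2x2.
#' @param B Monte Carlo replicates for the simulated Fisher p.
#' @return An `oe_result` with `test_p`, `test_used`, `statistic`, `df`,
#'   and when requested `cell_p` / `cell_q` matrices.
#' @export
oe_significance <- function(table, method = c("auto", "chisq", "fisher"),
                            per_cell = FALSE, seed = 0L, B = 10000L) {
  stopifnot(inherits(table, "composition_table"))
  method <- match.arg(method)
  if (table$N == 0) stop("composition table has N = 0", call. = FALSE)
  res <- oe_ratio(table)
  pick <- function(O) {
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    if (method == "chisq" || (method == "auto" && all(E >= 5))) "chisq" else "fisher"
  }
  run_test <- function(O) {
    used <- pick(O)
    if (used == "chisq") {
      ht <- suppressWarnings(stats::chisq.test(O, correct = FALSE))
      list(p = unname(ht$p.value), statistic = unname(ht$statistic),
           df = unname(ht$parameter), used = "chisq")
    } else {
      if (nrow(O) == 2 && ncol(O) == 2) {
        ht <- stats::fisher.test(O)
      } else {
        set.seed(seed)
        ht <- stats::fisher.test(O, simulate.p.value = TRUE, B = B)
      }
      list(p = unname(ht$p.value), statistic = NA_real_, df = NA_real_,
           used = "fisher")
    }
  }
  tw <- run_test(table$O)
  res$test_p <- tw$p
  res$statistic <- tw$statistic
  res$df <- tw$df
  res$test_used <- tw$used
  if (per_cell) {
    O <- table$O
    cell_p <- matrix(NA_real_, nrow(O), ncol(O), dimnames = dimnames(O))
    for (i in seq_len(nrow(O))) {
      for (j in seq_len(ncol(O))) {
        collapsed <- matrix(c(O[i, j], table$r[i] - O[i, j],
                              table$c[j] - O[i, j],
                              table$N - table$r[i] - table$c[j] + O[i, j]),
                            nrow = 2, byrow = TRUE)
        cell_p[i, j] <- run_test(collapsed)$p
      }
    }
    res$cell_p <- cell_p
    res$cell_q <- matrix(stats::p.adjust(cell_p, method = "BH"),
                         nrow(O), ncol(O), dimnames = dimnames(O))
  }
  res
}

#' Mean per-sample cell-type proportions by group
#'
#' Computes each sample's cell-type proportions (summing to one within a
#' sample) and then averages them without weighting within each group, so
#' deeply sequenced samples do not dominate the group mean.
#'
#' @param atlas A `cell_atlas`.
#' @param group_key Metadata column defining the groups (default
#'   `tissue_group`).
#' @param type_key Metadata column defining the cell types.
#' @return A list with `per_sample` (samples x types proportion matrix) and
#'   `group_mean` (groups x types matrix of unweighted means).
#' @export
proportion_summary <- function(atlas, group_key = "tissue_group",
                               type_key = "cell_type") {
  stopifnot(inherits(atlas, "cell_atlas"))
  for (key in c(group_key, type_key)) {
    if (!key %in% colnames(atlas$meta)) {
      stop("metadata has no column named: ", key, call. = FALSE)
    }
  }
  tab <- unclass(table(atlas$meta$sample_id, atlas$meta[[type_key]]))
  totals <- rowSums(tab)
  empty <- totals == 0
  if (any(empty)) {
    warning("excluding sample(s) with zero cells: ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
    totals <- totals[!empty]
  }
  per_sample <- tab / totals
  sample_group <- vapply(rownames(per_sample), function(s) {
    as.character(atlas$meta[[group_key]][atlas$meta$sample_id == s][1])
  }, character(1))
  groups <- sort(unique(sample_group))
  group_mean <- t(vapply(groups, function(g) {
    colMeans(per_sample[sample_group == g, , drop = FALSE])
  }, numeric(ncol(per_sample))))
  rownames(group_mean) <- groups
  list(per_sample = per_sample, sample_group = sample_group,
       group_mean = group_mean)
}

#' Binned-control gene-signature (module) score
#'
#' Scores each cell for each gene signature against expression-matched
#' control genes. Counts are library-size normalized to 10,000 per cell and
#' log1p-transformed; genes are ranked by mean normalized expression and
#' cut into `n_bins` equal-frequency bins; for every signature gene,
#' `n_controls` control genes are drawn from its bin (fixed seed), and the
#' score per cell is mean(signature genes) - mean(control genes).
#'
#' @param atlas A `cell_atlas`.
#' @param signatures Named list mapping signature name to a character
#'   vector of gene ids.
#' @param n_bins Number of expression bins (default 25).
#' @param n_controls Control genes sampled per signature gene (default 100).
#' @param seed Seed for control-gene sampling.
#' @return A `signature_scores` object: list with `scores` (cells x
#'   signatures matrix) and the parameters used.
#' @export
score_signature <- function(atlas, signatures, n_bins = 25L,
                            n_controls = 100L, seed = 0L) {
  stopifnot(inherits(atlas, "cell_atlas"), is.list(signatures))
  lib <- Matrix::colSums(atlas$counts)
  if (any(lib == 0)) stop("cell(s) with zero total counts; run QC first",
                          call. = FALSE)
  norm <- atlas$counts %*% Matrix::Diagonal(x = 1e4 / lib)
  norm@x <- log1p(norm@x)
  gene_means <- Matrix::rowMeans(norm)
  n_bins <- min(n_bins, length(gene_means))
  bins <- cut(rank(gene_means, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- atlas$gene_ids
  scores <- matrix(NA_real_, ncol(norm), length(signatures),
                   dimnames = list(colnames(atlas$counts), names(signatures)))
  set.seed(seed)
  for (sig in names(signatures)) {
    genes <- intersect(signatures[[sig]], atlas$gene_ids)
    if (length(genes) == 0) {
      stop("signature has no genes in the atlas: ", sig, call. = FALSE)
    }
    ctrl <- unlist(lapply(genes, function(g) {
      pool <- names(bins)[bins == bins[g]]
      sample(pool, n_controls, replace = length(pool) < n_controls)
    }), use.names = FALSE)
    sig_mean <- Matrix::colMeans(norm[match(genes, atlas$gene_ids), , drop = FALSE])
    ctrl_mean <- Matrix::colMeans(norm[match(ctrl, atlas$gene_ids), , drop = FALSE])
    scores[, sig] <- sig_mean - ctrl_mean
  }
  structure(list(scores = scores, signatures = signatures,
                 n_bins = n_bins, n_controls = n_controls, seed = seed),
            class = "signature_scores")
}
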