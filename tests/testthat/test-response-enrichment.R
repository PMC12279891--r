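test_that("pseudobulk sums counts per sample and applies min_cells", {
  counts <- matrix(c(1, 2, 3, 4), 2)  # cells (1,2) and (3,4)
  atlas <- cell_atlas(counts, data.frame(
    cell_id = c("c1", "c2"), cell_type = "T", sample_id = "s1",
    tissue_group = "tumor"))
  pb <- build_pseudobulk(atlas, "T", min_cells = 2)
  expect_equal(unname(pb$counts["s1", ]), c(4, 6))

  expect_warning(expect_error(build_pseudobulk(atlas, "T", min_cells = 3),
                              "no sample retains"),
                 "dropping")

  # permutation invariance over cell order
  perm_atlas <- subset_cells(atlas, 2:1)
  pb_perm <- build_pseudobulk(perm_atlas, "T", min_cells = 2)
  expect_equal(pb_perm$counts, pb$counts)
})

test_that("CPM normalization preserves proportions and maps zero to zero", {
  pb <- structure(list(counts = matrix(c(2, 3, 0, 5), 1,
                                       dimnames = list("s1", paste0("g", 1:4))),
                       group = "tumor"), class = "pseudobulk")
  norm <- normalize_cpm(pb)
  expect_equal(unname(norm["s1", 1:2]), log2(c(2, 3) / 10 * 1e6 + 1))
  expect_equal(unname(norm["s1", 3]), 0)

  zero <- structure(list(counts = matrix(0, 1, 2,
                                         dimnames = list("s0", c("a", "b"))),
                         group = "x"), class = "pseudobulk")
  expect_error(normalize_cpm(zero), "s0")
})

test_that("per-gene Welch t matches stats::t.test and handles flat genes", {
  set.seed(44)
  xa <- matrix(rnorm(60, 5), 6)
  xb <- matrix(rnorm(50, 5.5), 5)
  wt <- tmeniche:::welch_t_columns(xa, xb)
  for (j in 1:10) {
    ref <- stats::t.test(xa[, j], xb[, j])
    expect_equal(wt$t[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(wt$p[j], ref$p.value, tolerance = 1e-12)
  }
  flat <- tmeniche:::welch_t_columns(matrix(3, 4, 1), matrix(3, 4, 1))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)
})

test_that("differential expression selects planted program genes", {
  spec <- cytokine_sim_spec(n_cytokines = 5, n_genes = 400,
                            program_size = 20, program_log2fc = 2,
                            planted_cytokine = "IL-2",
                            n_samples_per_group = 6, seed = 3)
  sim <- simulate_cytokine_dictionary(spec)
  pb <- build_pseudobulk(sim$atlas, "target")
  de <- differential_expression(pb, "tumor", "healthy")
  expect_gte(mean(de$selected[sim$truth$planted_genes]), 0.9)
  expect_true(all(de$p[de$selected] < 0.05))

  # too few samples in a group is a hard error
  small <- sim$atlas
  keep <- small$meta$sample_id %in% c("tumor_s1", "healthy_s1", "healthy_s2")
  small <- subset_cells(small, keep)
  pb_small <- build_pseudobulk(small, "target")
  expect_error(differential_expression(pb_small, "tumor", "healthy"),
               ">= 2 samples")
})

test_that("cosine scoring reproduces worked values and invariances", {
  dict <- cytokine_dictionary(rbind(c1 = c(1, 1, 0), c2 = c(0, 1, 1)),
                              gene_ids = c("g1", "g2", "g3"))
  degs <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(1, 0, 1),
                     p = 0.01, selected = TRUE)
  class(degs) <- c("deg_table", "data.frame")
  res <- irea_score(degs, dict)
  # v = (1, 0, 1) against (1, 1, 0) and (0, 1, 1): both cosines are 0.5
  expect_equal(res$cosine, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(res$cosine[1], oracle_cosine(c(1, 0, 1), c(1, 1, 0)),
               tolerance = 1e-12)

  self_dict <- cytokine_dictionary(rbind(same = c(2, -1, 3),
                                         orth = c(0, 3, 1),
                                         flat = c(0, 0, 0)),
                                   gene_ids = c("g1", "g2", "g3"))
  v_degs <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(2, -1, 3),
                       p = 0.01, selected = TRUE)
  class(v_degs) <- c("deg_table", "data.frame")
  r2 <- irea_score(v_degs, self_dict)
  expect_equal(r2$cosine[1], 1, tolerance = 1e-12)
  expect_equal(r2$cosine[2], 0, tolerance = 1e-12)    # orthogonal
  expect_true(is.na(r2$cosine[3]))                     # zero signature

  # scale invariance and antisymmetry under negation
  v_scaled <- v_degs
  v_scaled$log2fc <- v_scaled$log2fc * 13
  expect_equal(irea_score(v_scaled, self_dict)$cosine, r2$cosine,
               tolerance = 1e-12)
  v_neg <- v_degs
  v_neg$log2fc <- -v_neg$log2fc
  expect_equal(irea_score(v_neg, self_dict)$cosine[1:2], -r2$cosine[1:2],
               tolerance = 1e-12)

  none <- data.frame(gene = "absent", log2fc = 1, p = 0.01, selected = TRUE)
  class(none) <- c("deg_table", "data.frame")
  expect_error(irea_score(none, dict), "no DEGs in dictionary")
})

test_that("permutation p-values respect the floor and the symmetric null", {
  set.seed(10)
  # with 30 distinct values and the signature equal to the DEG vector, only
  # the identity permutation ties the observed cosine of 1, so every null
  # draw falls below it and the p-value sits at its floor
  v <- sort(rnorm(30))
  dict <- cytokine_dictionary(rbind(self = v, other = rev(v)),
                              gene_ids = paste0("g", 1:30))
  degs <- data.frame(gene = paste0("g", 1:30), log2fc = v, p = 0.01,
                     selected = TRUE)
  class(degs) <- c("deg_table", "data.frame")
  res <- irea_permutation_fdr(degs, dict, n_perm = 500, seed = 1)
  expect_equal(res$perm_p[res$cytokine == "self"], 1 / 501)
  expect_error(irea_permutation_fdr(degs, dict, n_perm = 50), "n_perm")

  # observed cosine of exactly 0 against a symmetric permutation null
  set.seed(2)
  m <- 40
  s <- rep(c(1, -1), m / 2)
  raw <- rnorm(m)
  v0 <- raw - sum(raw * s) / sum(s * s) * s  # orthogonal to the signature
  sym_dict <- cytokine_dictionary(
    matrix(s, 1, dimnames = list("c", paste0("g", 1:m))))
  sym_degs <- data.frame(gene = paste0("g", 1:m), log2fc = v0,
                         p = 0.01, selected = TRUE)
  class(sym_degs) <- c("deg_table", "data.frame")
  res_sym <- irea_permutation_fdr(sym_degs, sym_dict, n_perm = 1000, seed = 3)
  expect_equal(res_sym$cosine, 0, tolerance = 1e-12)
  expect_gt(res_sym$perm_p, 0.4)
  expect_lt(res_sym$perm_p, 0.6)
})

test_that("the planted cytokine wins the end-to-end enrichment", {
  spec <- cytokine_sim_spec(n_cytokines = 86, n_genes = 400,
                            program_size = 20, program_log2fc = 2,
                            planted_cytokine = "IL-2",
                            n_samples_per_group = 6, seed = 19)
  sim <- simulate_cytokine_dictionary(spec)
  pb <- build_pseudobulk(sim$atlas, "target")
  de <- differential_expression(pb, "tumor", "healthy")
  res <- irea_permutation_fdr(de, sim$dictionary, n_perm = 2000, seed = 1)
  top <- res$cytokine[which.max(res$cosine)]
  expect_equal(top, "IL-2")
  expect_lt(res$q[res$cytokine == "IL-2"], 0.05)
  expect_equal(sum(res$q < 0.05, na.rm = TRUE), 1L)
})

test_that("pseudobulk correlation handles exact and degenerate cases", {
  x <- seq_len(10)
  norm <- cbind(gx = x, gy = 2 * x + 1, gneg = -x, gflat = rep(3, 10))
  rownames(norm) <- paste0("s", 1:10)
  expect_equal(pseudobulk_correlation(norm, "gx", "gy")$r, 1, tolerance = 1e-12)
  expect_equal(pseudobulk_correlation(norm, "gx", "gneg")$r, -1,
               tolerance = 1e-12)
  flat <- pseudobulk_correlation(norm, "gx", "gflat")
  expect_true(flat$undefined)
  expect_true(is.na(flat$r))
  expect_error(pseudobulk_correlation(norm, "gx", "nope"), "nope")
  expect_error(pseudobulk_correlation(norm[1:2, ], "gx", "gy"), "3 samples")

  sp <- pseudobulk_correlation(norm, "gx", "gy", method = "spearman")
  expect_equal(sp$r, 1, tolerance = 1e-12)
})

test_that("a planted sample-level correlation of 0.8 is recovered", {
  set.seed(123)
  hits <- replicate(30, {
    z <- rnorm(18)
    x <- z
    y <- 0.8 * z + sqrt(1 - 0.8^2) * rnorm(18)
    norm <- cbind(STAT5A = x, IL2RA = y)
    rownames(norm) <- paste0("s", 1:18)
    abs(pseudobulk_correlation(norm, "STAT5A", "IL2RA")$r - 0.8) <= 0.2
  })
  expect_gte(mean(hits), 0.9)
})
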