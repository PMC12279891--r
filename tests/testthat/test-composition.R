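test_that("tabulate_composition counts labels and validates keys", {
  counts <- matrix(1L, 2, 4)
  atlas <- cell_atlas(counts, data.frame(
    cell_id = paste0("c", 1:4),
    cell_type = c("A", "A", "B", "B"),
    sample_id = "s1",
    tissue_group = c("t", "t", "t", "h")))
  tab <- tabulate_composition(atlas)
  expect_equal(unname(tab$O), matrix(c(0, 1, 2, 1), 2),
               ignore_attr = TRUE)
  expect_equal(tab$N, 4)
  expect_equal(tab$r, rowSums(tab$O))
  expect_equal(tab$c, colSums(tab$O))

  # degenerate but valid: same key on both axes gives a diagonal table
  diag_tab <- tabulate_composition(atlas, "cell_type", "cell_type")
  expect_equal(unname(diag_tab$O), diag(c(2, 2)), ignore_attr = TRUE)

  expect_error(tabulate_composition(atlas, "nope", "tissue_group"), "nope")
})

test_that("oe_ratio evaluates the observed/expected formula", {
  res <- oe_ratio(composition_table(matrix(c(30, 10, 10, 30), 2,
                                           byrow = TRUE)))
  expect_equal(unname(res$E), matrix(20, 2, 2))
  expect_equal(unname(res$ratio), matrix(c(1.5, 0.5, 0.5, 1.5), 2,
                                         byrow = TRUE))

  uniform <- oe_ratio(composition_table(matrix(10, 2, 2)))
  expect_equal(unname(uniform$ratio), matrix(1, 2, 2))

  one_col <- oe_ratio(composition_table(matrix(c(5, 7), ncol = 1)))
  expect_equal(unname(one_col$ratio), matrix(1, 2, 1))

  # conservation and the zero-margin undefined flag
  set.seed(2)
  for (i in 1:20) {
    O <- matrix(rpois(12, 8), 3, 4)
    O[1, ] <- 0L
    r <- oe_ratio(composition_table(O))
    expect_equal(sum(r$E), sum(O))
    expect_true(all(is.na(r$ratio[1, ])))
    expect_true(all(r$undefined[1, ]))
  }
})

test_that("permuting rows and columns permutes the ratio identically", {
  set.seed(5)
  O <- matrix(rpois(12, 20), 3, 4)
  base <- oe_ratio(composition_table(O))$ratio
  pr <- sample(3); pc <- sample(4)
  perm <- oe_ratio(composition_table(O[pr, pc]))$ratio
  expect_equal(perm, base[pr, pc], ignore_attr = TRUE)
})

test_that("oe_significance matches the textbook chi-square and exact Fisher", {
  O <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  res <- oe_significance(composition_table(O))
  expect_equal(res$test_used, "chisq")
  expect_equal(res$statistic, 20, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$statistic, oracle_chisq_stat(O), tolerance = 1e-10)

  sparse <- matrix(c(2, 1, 1, 2), 2)
  fres <- oe_significance(composition_table(sparse))
  expect_equal(fres$test_used, "fisher")  # some E below 5 -> exact test
  expect_equal(fres$test_p, 1, tolerance = 1e-10)
  expect_equal(fres$test_p, oracle_fisher_2x2(sparse), tolerance = 1e-10)

  flat <- oe_significance(composition_table(matrix(10, 2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$test_p, 1)
})

test_that("2x2 significance agrees with enumeration oracles across tables", {
  set.seed(8)
  for (i in 1:25) {
    O <- matrix(rpois(4, 6) + 1L, 2, 2)
    tab <- composition_table(O)
    chs <- oe_significance(tab, method = "chisq")
    expect_equal(chs$statistic, oracle_chisq_stat(O), tolerance = 1e-10)
    fis <- oe_significance(tab, method = "fisher")
    expect_equal(fis$test_p, oracle_fisher_2x2(O), tolerance = 1e-8)
  }
})

test_that("per-cell significance returns BH-adjusted 2x2 collapses", {
  O <- matrix(c(40, 10, 10, 40, 25, 25), 3, 2, byrow = TRUE)
  res <- oe_significance(composition_table(O), per_cell = TRUE)
  expect_equal(dim(res$cell_p), dim(O))
  expect_equal(as.vector(res$cell_q), oracle_bh(as.vector(res$cell_p)))
})

test_that("proportion_summary averages per-sample proportions unweighted", {
  counts <- matrix(1L, 2, 6)
  atlas <- cell_atlas(counts, data.frame(
    cell_id = paste0("c", 1:6),
    cell_type = c("A", "A", "A", "B", "A", "B"),
    sample_id = c("s1", "s1", "s1", "s1", "s2", "s2"),
    tissue_group = "tumor"))
  ps <- proportion_summary(atlas)
  expect_equal(unname(ps$per_sample["s1", ]), c(0.75, 0.25))
  expect_true(all(abs(rowSums(ps$per_sample) - 1) < 1e-12))
  # s1 = (0.75, 0.25), s2 = (0.5, 0.5): unweighted mean despite s1 size
  expect_equal(unname(ps$group_mean["tumor", ]), c(0.625, 0.375))
})

test_that("planted 2x enrichment appears in group mean proportions", {
  spec <- atlas_sim_spec(
    n_genes = 3, cell_types = c("Treg", "Teff", "Mac"),
    samples_per_group = c(healthy = 3, tumor = 3),
    base_cells_per_sample = 1500,
    enrichment = data.frame(cell_type = "Treg", group = "tumor", fold = 2),
    seed = 17)
  sim <- simulate_atlas(spec)
  ps <- proportion_summary(sim$atlas)
  ratio <- ps$group_mean["tumor", "Treg"] / ps$group_mean["healthy", "Treg"]
  # planted probabilities give (1/2) / (1/3) = 1.5 after renormalization
  expect_equal(ratio, 1.5, tolerance = 0.1)
})

test_that("signature scores are zero for constant expression and reproducible", {
  counts <- matrix(5L, 40, 12)
  atlas <- make_toy_atlas(counts, "T")
  sigs <- list(sig_a = paste0("gene", 1:5))
  sc <- score_signature(atlas, sigs, n_bins = 5, n_controls = 10, seed = 1)
  expect_true(all(abs(sc$scores) < 1e-12))

  sc2 <- score_signature(atlas, sigs, n_bins = 5, n_controls = 10, seed = 1)
  expect_identical(sc$scores, sc2$scores)

  expect_error(score_signature(atlas, list(bad = c("nope1", "nope2"))),
               "bad")
})

test_that("planted signature shift is recovered by the module score", {
  # signature genes take distinct baseline means spread through the
  # unshifted range, so each lands in a control bin dominated by
  # unshifted genes rather than by the signature itself
  genes <- 1:10
  set.seed(61)
  base_mu <- c(seq(9, 15, length.out = 10), runif(390, 8, 30))
  spec <- atlas_sim_spec(
    n_genes = 400, cell_types = "T",
    samples_per_group = c(healthy = 2, tumor = 2),
    base_cells_per_sample = 150, nb_mean = base_mu, nb_dispersion = 0.2,
    signature_shift = list(list(genes = genes, group = "tumor",
                                cell_type = "T", log2fc = 1)),
    seed = 23)
  sim <- simulate_atlas(spec)
  sc <- score_signature(sim$atlas, list(shifted = paste0("gene", genes)),
                        seed = 2)
  grp <- sim$atlas$meta$tissue_group
  diff <- mean(sc$scores[grp == "tumor", 1]) -
    mean(sc$scores[grp == "healthy", 1])
  # oracle expectation: E[log1p(k/lib*1e4)] difference under NB at the
  # shifted vs baseline mean, fixed at the expected library size per group
  lib_h <- sum(base_mu)
  lib_t <- lib_h + sum(base_mu[genes])
  expected <- mean(vapply(base_mu[genes], function(mu) {
    oracle_expected_lognorm(2 * mu, size = 5, lib = lib_t) -
      oracle_expected_lognorm(mu, size = 5, lib = lib_h)
  }, numeric(1)))
  # each bin of ~16 genes contains one shifted gene, so about 1/16 of
  # control draws carry the shift and bias the score down by ~0.04
  expect_lt(abs(diff - expected), 0.1)
  expect_gt(diff, 0.3)
})
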