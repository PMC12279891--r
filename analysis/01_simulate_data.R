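#!/usr/bin/env Rscript

# Step 1: simulate the study's input artifacts with known ground truth.
#
# Produces a labelled single-cell atlas (two tissue groups, planted Treg
# enrichment in tumor plus an exhaustion-like signature shift) and an
# 86-cytokine signature dictionary with an IL-2-like program planted in the
# tumor group. Later steps read these back through the package's IO layer.

suppressPackageStartupMessages(library(tmeniche))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Atlas: 3 samples per group, Treg doubled in tumor, genes 1-10 shifted in
## tumor T cells to mimic an activated program.
set.seed(100)
base_mu <- c(seq(9, 15, length.out = 10), runif(90, 8, 30))
atlas_spec <- atlas_sim_spec(
  n_genes = 100,
  cell_types = c("Treg", "Teff", "Trm", "Mac", "Epi"),
  samples_per_group = c(healthy = 3, tumor = 3),
  base_cells_per_sample = 800,
  nb_mean = base_mu, nb_dispersion = 0.2,
  enrichment = data.frame(cell_type = "Treg", group = "tumor", fold = 2),
  signature_shift = list(list(genes = 1:10, group = "tumor",
                              cell_type = "Treg", log2fc = 1)),
  seed = 100)
sim <- simulate_atlas(atlas_spec)
write_atlas(sim$atlas, file.path(out, "atlas"))
utils::write.table(sim$truth$realized_composition,
                   file.path(out, "atlas_truth_composition.tsv"),
                   sep = "\t", quote = FALSE)
cat(sprintf("atlas: %d cells x %d genes, groups %s\n",
            nrow(sim$atlas$meta), nrow(sim$atlas$counts),
            paste(unique(sim$atlas$meta$tissue_group), collapse = "/")))
cat(sprintf("planted: Treg 2x in tumor; genes 1-10 shifted log2fc=1 in tumor Treg\n"))

## Cytokine dictionary + response atlas: IL-2-like program planted in tumor.
cyto_spec <- cytokine_sim_spec(
  n_cytokines = 86, n_genes = 400, program_size = 20, program_log2fc = 2,
  planted_cytokine = "IL-2", n_samples_per_group = 6, seed = 200)
cyto <- simulate_cytokine_dictionary(cyto_spec)
utils::write.table(
  data.frame(cytokine = rownames(cyto$dictionary$signatures),
             cyto$dictionary$signatures, check.names = FALSE),
  file.path(out, "cytokine_dictionary.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
write_atlas(cyto$atlas, file.path(out, "response_atlas"))
writeLines(paste0("gene", cyto$truth$planted_genes),
           file.path(out, "response_truth_program_genes.txt"))
cat(sprintf("dictionary: %d cytokines x %d genes; planted cytokine IL-2 (%d program genes, log2fc 2)\n",
            nrow(cyto$dictionary$signatures), ncol(cyto$dictionary$signatures),
            length(cyto$truth$planted_genes)))
cat("wrote", out, "\n")
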