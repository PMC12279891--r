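#' Specification for a simulated single-cell atlas
#'
#' Defines a multi-group atlas with planted cell-type composition shifts,
#' negative-binomial counts, optional marker-gene boosts and optional
#' signature-gene shifts. Counts use the NB parameterisation
#' `Var = mu + phi * mu^2` with a single shared dispersion `phi`
#' (`nb_dispersion`).
#'
#' @param n_genes Number of genes.
#' @param cell_types Character vector of cell-type names.
#' @param samples_per_group Named integer vector: group -> number of
#'   samples (e.g. `c(healthy = 3, tumor = 3)`).
#' @param base_cells_per_sample Cells simulated per sample.
#' @param base_props Baseline cell-type proportions (default uniform).
#' @param enrichment Optional data.frame with columns `cell_type`,
#'   `group`, `fold` giving multiplicative composition fold-factors
#'   (all > 0); types/groups not listed keep factor 1.
#' @param nb_mean Baseline NB mean per gene per cell; a scalar or a
#'   vector recycled over genes.
#' @param nb_dispersion NB dispersion `phi` (`size = 1/phi`).
#' @param marker_genes Optional named list: cell type -> gene indices
#'   whose mean is boosted `2^marker_log2fc` in that type. Sets must be
#'   disjoint.
#' @param marker_log2fc Log2 boost for marker genes.
#' @param signature_shift Optional list of `list(genes=, group=,
#'   cell_type=, log2fc=)` entries multiplying the NB mean of `genes` by
#'   `2^log2fc` for cells of that type in that group.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return An `atlas_sim_spec` list.
#' @export
atlas_sim_spec <- function(n_genes, cell_types, samples_per_group,
                           base_cells_per_sample,
                           base_props = NULL, enrichment = NULL,
                           nb_mean = 2, nb_dispersion = 0.5,
                           marker_genes = NULL, marker_log2fc = 1,
                           signature_shift = NULL, seed = 0L) {
  if (is.null(names(samples_per_group))) {
    stop("samples_per_group must be a named vector (group -> n samples)",
         call. = FALSE)
  }
  if (is.null(base_props)) {
    base_props <- rep(1 / length(cell_types), length(cell_types))
  }
  names(base_props) <- cell_types
  if (!is.null(enrichment)) {
    if (any(enrichment$fold <= 0)) stop("enrichment fold-factors must be > 0",
                                        call. = FALSE)
    bad <- setdiff(enrichment$cell_type, cell_types)
    if (length(bad)) stop("unknown cell type in enrichment: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(marker_genes)) {
    all_markers <- unlist(marker_genes)
    if (anyDuplicated(all_markers)) stop("marker gene sets must be disjoint",
                                         call. = FALSE)
    if (any(all_markers > n_genes)) stop("marker gene index out of range",
                                         call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), cell_types = cell_types,
                 samples_per_group = samples_per_group,
                 base_cells_per_sample = as.integer(base_cells_per_sample),
                 base_props = base_props, enrichment = enrichment,
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 marker_genes = marker_genes, marker_log2fc = marker_log2fc,
                 signature_shift = signature_shift, seed = as.integer(seed)),
            class = "atlas_sim_spec")
}

# Cell-type probabilities per group under the planted fold-factors.
planted_type_probs <- function(spec) {
  groups <- names(spec$samples_per_group)
  fold <- matrix(1, length(spec$cell_types), length(groups),
                 dimnames = list(spec$cell_types, groups))
  if (!is.null(spec$enrichment)) {
    for (i in seq_len(nrow(spec$enrichment))) {
      fold[spec$enrichment$cell_type[i], spec$enrichment$group[i]] <-
        spec$enrichment$fold[i]
    }
  }
  probs <- spec$base_props * fold
  sweep(probs, 2, colSums(probs), "/")
}

#' Simulate a single-cell atlas with planted composition and expression
#'
#' Cell types per group follow a multinomial whose probabilities are the
#' baseline proportions times the planted enrichment fold-factors
#' (renormalized); counts are negative-binomial with marker and signature
#' boosts applied to the NB mean. The returned truth records every
#' planted parameter plus the realized composition and the
#' expectation-derived Ro/e matrix.
#'
#' @param spec An [atlas_sim_spec()].
#' @return List with `atlas` (a `cell_atlas`) and `truth`.
#' @export
simulate_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_sim_spec"))
  if (spec$base_cells_per_sample <= 0) {
    stop("base_cells_per_sample must give every sample at least one cell",
         call. = FALSE)
  }
  set.seed(spec$seed)
  probs <- planted_type_probs(spec)
  groups <- names(spec$samples_per_group)
  meta_list <- list()
  for (g in groups) {
    for (s in seq_len(spec$samples_per_group[[g]])) {
      n <- spec$base_cells_per_sample
      types <- sample(spec$cell_types, n, replace = TRUE, prob = probs[, g])
      meta_list[[length(meta_list) + 1L]] <- data.frame(
        cell_type = types, sample_id = sprintf("%s_s%d", g, s),
        tissue_group = g, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta_list)
  meta$cell_id <- sprintf("cell%06d", seq_len(nrow(meta)))
  size <- 1 / spec$nb_dispersion
  counts <- matrix(0L, spec$n_genes, nrow(meta))
  combos <- unique(meta[, c("cell_type", "tissue_group")])
  combos <- combos[order(combos$cell_type, combos$tissue_group), , drop = FALSE]
  for (i in seq_len(nrow(combos))) {
    ct <- combos$cell_type[i]; g <- combos$tissue_group[i]
    mu <- rep(spec$nb_mean, length.out = spec$n_genes)
    if (!is.null(spec$marker_genes[[ct]])) {
      mu[spec$marker_genes[[ct]]] <- mu[spec$marker_genes[[ct]]] *
        2^spec$marker_log2fc
    }
    for (shift in spec$signature_shift) {
      if (shift$group == g && shift$cell_type == ct) {
        mu[shift$genes] <- mu[shift$genes] * 2^shift$log2fc
      }
    }
    cells <- which(meta$cell_type == ct & meta$tissue_group == g)
    counts[, cells] <- stats::rnbinom(spec$n_genes * length(cells),
                                      size = size, mu = mu)
  }
  atlas <- cell_atlas(counts, meta[, c("cell_id", "cell_type", "sample_id",
                                       "tissue_group")])
  group_cells <- spec$samples_per_group * spec$base_cells_per_sample
  expected_O <- sweep(probs, 2, group_cells[colnames(probs)], "*")
  truth <- list(spec = spec,
                type_probs = probs,
                realized_composition =
                  unclass(table(meta$cell_type, meta$tissue_group)),
                expected_counts = expected_O,
                expected_oe = oe_ratio(composition_table(expected_O))$ratio)
  list(atlas = atlas, truth = truth)
}

#' Specification for a simulated spatial abundance map
#'
#' Beads live in the unit square (uniform or grid layout); each bead gets
#' the composition vector of the niche region containing it (circular
#' regions evaluated in order, with a background composition elsewhere)
#' plus zero-truncated Gaussian noise. An optional colocalization pair
#' rewrites one type as a linear function of another plus noise.
#'
#' @param n_beads Number of beads.
#' @param niche_regions List of `list(center = c(x, y), radius =, composition =
#'   named numeric)` regions.
#' @param background_composition Named non-negative vector used outside
#'   every region; its names define the cell types.
#' @param layout `"uniform"` or `"grid"`.
#' @param noise_sd Gaussian noise SD on abundance (truncated at 0).
#' @param coloc_pair Optional `list(type_a =, type_b =, slope =, noise_sd =)`
#'   setting `type_b = slope * type_a + noise` after region assignment.
#' @param seed Integer seed.
#' @return A `spatial_sim_spec` list.
#' @export
spatial_sim_spec <- function(n_beads, niche_regions = list(),
                             background_composition,
                             layout = c("uniform", "grid"),
                             noise_sd = 0.05, coloc_pair = NULL, seed = 0L) {
  layout <- match.arg(layout)
  types <- names(background_composition)
  if (is.null(types) || length(types) == 0) {
    stop("background_composition must be a named vector", call. = FALSE)
  }
  if (any(background_composition < 0)) {
    stop("composition vectors must be non-negative", call. = FALSE)
  }
  for (reg in niche_regions) {
    if (is.null(reg$composition) || length(reg$composition) == 0) {
      stop("region with empty composition", call. = FALSE)
    }
    if (any(reg$composition < 0)) stop("composition vectors must be non-negative",
                                       call. = FALSE)
    if (!setequal(names(reg$composition), types)) {
      stop("region composition names must match background_composition",
           call. = FALSE)
    }
  }
  if (!is.null(coloc_pair)) {
    stopifnot(all(c("type_a", "type_b", "slope", "noise_sd") %in%
                    names(coloc_pair)),
              all(c(coloc_pair$type_a, coloc_pair$type_b) %in% types))
  }
  structure(list(n_beads = as.integer(n_beads), niche_regions = niche_regions,
                 background_composition = background_composition,
                 cell_types = types, layout = layout, noise_sd = noise_sd,
                 coloc_pair = coloc_pair, seed = as.integer(seed)),
            class = "spatial_sim_spec")
}

#' Simulate a spatial abundance map with planted niches
#'
#' @param spec A [spatial_sim_spec()].
#' @return List with `spatial` (a `spatial_map`) and `truth` holding the
#'   per-bead niche label (`0` = background, `1..R` = region index) and
#'   the planted spec.
#' @export
simulate_spatial <- function(spec) {
  stopifnot(inherits(spec, "spatial_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_beads
  if (spec$layout == "grid") {
    side <- ceiling(sqrt(n))
    grid <- expand.grid(x = seq(0, 1, length.out = side),
                        y = seq(0, 1, length.out = side))
    coords <- as.matrix(grid[seq_len(n), ])
  } else {
    coords <- cbind(x = stats::runif(n), y = stats::runif(n))
  }
  niche <- integer(n)  # 0 = background
  for (r in seq_along(spec$niche_regions)) {
    reg <- spec$niche_regions[[r]]
    inside <- (coords[, "x"] - reg$center[1])^2 +
      (coords[, "y"] - reg$center[2])^2 <= reg$radius^2
    niche[inside & niche == 0L] <- r
  }
  types <- spec$cell_types
  abundance <- matrix(0, n, length(types), dimnames = list(NULL, types))
  for (i in seq_len(n)) {
    base <- if (niche[i] == 0L) spec$background_composition else
      spec$niche_regions[[niche[i]]]$composition[types]
    abundance[i, ] <- base
  }
  if (spec$noise_sd > 0) {
    abundance <- pmax(abundance +
                        matrix(stats::rnorm(length(abundance), 0, spec$noise_sd),
                               nrow = n), 0)
  }
  if (!is.null(spec$coloc_pair)) {
    cp <- spec$coloc_pair
    abundance[, cp$type_b] <- pmax(cp$slope * abundance[, cp$type_a] +
                                     stats::rnorm(n, 0, cp$noise_sd), 0)
  }
  spatial <- spatial_map(coords = data.frame(x = coords[, "x"],
                                             y = coords[, "y"]),
                         abundance = abundance)
  truth <- list(spec = spec, niche = niche)
  list(spatial = spatial, truth = truth)
}

#' Specification for a simulated cytokine dictionary plus response atlas
#'
#' Builds a cytokines x genes signature dictionary (each cytokine's
#' program genes carry value `program_log2fc`, all other genes 0) and a
#' paired two-group atlas in which a single target cell type carries the
#' planted cytokine's program in the tumor group only.
#'
#' @param n_cytokines Number of cytokines (default 86, the immune
#'   dictionary's dimension).
#' @param n_genes Number of genes.
#' @param program_size Program genes per cytokine (overlap allowed).
#' @param program_log2fc Log2 induction of program genes.
#' @param planted_cytokine Name of the cytokine whose program the tumor
#'   group carries; substituted into the name list if absent.
#' @param n_samples_per_group Samples per tissue group.
#' @param cells_per_sample Target cells per sample (default 50).
#' @param nb_mean,nb_dispersion NB count parameters as in
#'   [atlas_sim_spec()].
#' @param cytokine_names Optional name list (length `n_cytokines`).
#' @param seed Integer seed.
#' @return A `cytokine_sim_spec` list.
#' @export
cytokine_sim_spec <- function(n_cytokines = 86L, n_genes, program_size,
                              program_log2fc, planted_cytokine,
                              n_samples_per_group, cells_per_sample = 50L,
                              nb_mean = 2, nb_dispersion = 0.4,
                              cytokine_names = NULL, seed = 0L) {
  if (program_size > n_genes) stop("program_size exceeds n_genes",
                                   call. = FALSE)
  if (is.null(cytokine_names)) {
    cytokine_names <- sprintf("cytokine%02d", seq_len(n_cytokines))
  }
  if (length(cytokine_names) != n_cytokines) {
    stop("cytokine_names must have length n_cytokines", call. = FALSE)
  }
  if (!planted_cytokine %in% cytokine_names) {
    cytokine_names[1] <- planted_cytokine
  }
  structure(list(n_cytokines = as.integer(n_cytokines),
                 n_genes = as.integer(n_genes),
                 program_size = as.integer(program_size),
                 program_log2fc = program_log2fc,
                 planted_cytokine = planted_cytokine,
                 n_samples_per_group = as.integer(n_samples_per_group),
                 cells_per_sample = as.integer(cells_per_sample),
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 cytokine_names = cytokine_names, seed = as.integer(seed)),
            class = "cytokine_sim_spec")
}

#' Simulate a cytokine dictionary and a planted-response atlas
#'
#' @param spec A [cytokine_sim_spec()].
#' @return List with `dictionary` (a `cytokine_dictionary`), `atlas` (a
#'   `cell_atlas` with tissue groups `tumor` and `healthy`, one `target`
#'   cell type) and `truth` recording the planted cytokine and its
#'   program genes.
#' @export
simulate_cytokine_dictionary <- function(spec) {
  stopifnot(inherits(spec, "cytokine_sim_spec"))
  set.seed(spec$seed)
  gene_ids <- paste0("gene", seq_len(spec$n_genes))
  S <- matrix(0, spec$n_cytokines, spec$n_genes,
              dimnames = list(spec$cytokine_names, gene_ids))
  programs <- vector("list", spec$n_cytokines)
  names(programs) <- spec$cytokine_names
  for (c in seq_len(spec$n_cytokines)) {
    programs[[c]] <- sort(sample.int(spec$n_genes, spec$program_size))
    S[c, programs[[c]]] <- spec$program_log2fc
  }
  dict <- cytokine_dictionary(S)
  planted_genes <- programs[[spec$planted_cytokine]]
  size <- 1 / spec$nb_dispersion
  meta_list <- list()
  counts_list <- list()
  for (g in c("healthy", "tumor")) {
    mu <- rep(spec$nb_mean, spec$n_genes)
    if (g == "tumor") {
      mu[planted_genes] <- mu[planted_genes] * 2^spec$program_log2fc
    }
    for (s in seq_len(spec$n_samples_per_group)) {
      nc <- spec$cells_per_sample
      counts_list[[length(counts_list) + 1L]] <-
        matrix(stats::rnbinom(spec$n_genes * nc, size = size, mu = mu),
               spec$n_genes, nc)
      meta_list[[length(meta_list) + 1L]] <- data.frame(
        cell_type = "target", sample_id = sprintf("%s_s%d", g, s),
        tissue_group = g, stringsAsFactors = FALSE)[rep(1, nc), ]
    }
  }
  counts <- do.call(cbind, counts_list)
  meta <- do.call(rbind, meta_list)
  meta$cell_id <- sprintf("cell%06d", seq_len(nrow(meta)))
  rownames(counts) <- gene_ids
  atlas <- cell_atlas(counts, meta[, c("cell_id", "cell_type", "sample_id",
                                       "tissue_group")])
  truth <- list(spec = spec, planted_cytokine = spec$planted_cytokine,
                planted_genes = planted_genes, programs = programs)
  list(dictionary = dict, atlas = atlas, truth = truth)
}
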