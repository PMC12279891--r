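# k-nearest-neighbor indices by Euclidean distance, ties broken by row
# index. Returns an n x k integer matrix; self is never included.
knn_index_matrix <- function(points, k) {
  n <- nrow(points)
  if (k >= n) stop(sprintf("need at least k+1 = %d rows, got %d", k + 1, n),
                   call. = FALSE)
  d <- as.matrix(stats::dist(points))
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    dv <- d[i, ]
    dv[i] <- Inf
    ord <- order(dv, seq_len(n))
    idx[i, ] <- ord[seq_len(k)]
  }
  idx
}

#' Neighborhood (cell community) composition around each bead
#'
#' For every bead, finds its `k` nearest beads by Euclidean distance on
#' the coordinates (ties broken by bead index) and averages the abundance
#' rows of the bead itself plus those neighbors — the bead's cell
#' community. With `k = 0` the community is the bead alone and the
#' composition equals the raw abundance.
#'
#' @param spatial A `spatial_map`.
#' @param k Number of nearest beads in the community (default 20).
#' @return A `neighborhood_composition`: list with `comp` (beads x cell
#'   types), `k`, `coords`, `bead_ids`.
#' @export
knn_composition <- function(spatial, k = 20L) {
  stopifnot(inherits(spatial, "spatial_map"))
  k <- as.integer(k)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  n <- nrow(spatial$abundance)
  if (n < k + 1) {
    stop(sprintf("need at least k+1 = %d beads, got %d", k + 1, n),
         call. = FALSE)
  }
  if (k == 0) {
    comp <- spatial$abundance
  } else {
    nn <- knn_index_matrix(spatial$coords, k)
    comp <- spatial$abundance
    for (j in seq_len(k)) comp <- comp + spatial$abundance[nn[, j], , drop = FALSE]
    comp <- comp / (k + 1)
    rownames(comp) <- spatial$bead_ids
  }
  structure(list(comp = comp, k = k, coords = spatial$coords,
                 bead_ids = spatial$bead_ids),
            class = "neighborhood_composition")
}

#' Louvain clustering of beads into niches
#'
#' Builds a k-nearest-neighbor graph in community-composition space
#' (Euclidean, unweighted edges, mutualized by union) and runs Louvain
#' modularity optimization. Labels are contiguous integers `1..n_niches`
#' ordered by descending niche size; ties in size broken by smallest
#' member index.
#'
#' @param nc A `neighborhood_composition`.
#' @param graph_k Neighbors in the composition-space graph (default 30).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed Seed fixing the Louvain tie-breaks.
#' @return Integer vector of niche labels, one per bead, with attribute
#'   `n_niches`.
#' @export
cluster_niches <- function(nc, graph_k = 30L, resolution = 1, seed = 0L) {
  stopifnot(inherits(nc, "neighborhood_composition"))
  graph_k <- as.integer(graph_k)
  if (graph_k < 1) stop("graph_k must be >= 1", call. = FALSE)
  n <- nrow(nc$comp)
  graph_k <- min(graph_k, n - 1L)
  nn <- knn_index_matrix(nc$comp, graph_k)
  edges <- cbind(rep(seq_len(n), graph_k), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  raw <- as.integer(igraph::membership(cl))
  sizes <- table(raw)
  first_member <- vapply(names(sizes), function(m) min(which(raw == m)),
                         numeric(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes)
  labels <- relabel[raw]
  names(labels) <- nc$bead_ids
  attr(labels, "n_niches") <- length(sizes)
  labels
}

#' Per-niche cell-type enrichment by rank-sum test
#'
#' For each (niche, cell type) pair, compares that type's community
#' abundance inside the niche against all other beads with a two-sided
#' Wilcoxon rank-sum test, then applies Benjamini-Hochberg adjustment
#' across all pairs. A pair is flagged enriched when `q < alpha` and the
#' in-niche median exceeds the out-of-niche median.
#'
#' @param nc A `neighborhood_composition`.
#' @param labels Niche labels as returned by [cluster_niches()].
#' @param alpha FDR threshold (default 0.05).
#' @param min_beads Minimum beads for a niche to be tested (default 2).
#' @return A data.frame with columns `niche`, `cell_type`, `statistic`,
#'   `p`, `q`, `median_in`, `median_out`, `direction`, `enriched`, plus an
#'   attribute `skipped` listing untested niches.
#' @export
niche_enrichment <- function(nc, labels, alpha = 0.05, min_beads = 2L) {
  stopifnot(inherits(nc, "neighborhood_composition"))
  labels <- as.integer(labels)
  niches <- sort(unique(labels))
  if (length(niches) < 2) stop(">= 2 niches required", call. = FALSE)
  sizes <- table(labels)
  skipped <- as.integer(names(sizes)[sizes < min_beads])
  if (length(skipped) > 0) {
    warning("skipping niche(s) with fewer than ", min_beads, " beads: ",
            paste(skipped, collapse = ", "))
  }
  tested <- setdiff(niches, skipped)
  types <- colnames(nc$comp)
  rows <- vector("list", length(tested) * length(types))
  i <- 0L
  for (niche in tested) {
    inside <- labels == niche
    for (ct in types) {
      x <- nc$comp[inside, ct]
      y <- nc$comp[!inside, ct]
      ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
      i <- i + 1L
      rows[[i]] <- data.frame(
        niche = niche, cell_type = ct,
        statistic = unname(ht$statistic), p = ht$p.value,
        median_in = stats::median(x), median_out = stats::median(y),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(i)])
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$median_in > out$median_out, "up", "down")
  out$enriched <- out$q < alpha & out$direction == "up"
  attr(out, "skipped") <- skipped
  out
}
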