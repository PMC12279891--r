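#' Reference simulation scenarios
#'
#' Canonical study conditions used throughout the package's recovery
#' analyses, so that tests, the analysis scripts and the acceptance
#' checks all exercise the same planted ground truth.
#'
#' `three_niche_scenario()` lays out three broad contiguous domains
#' (left band, right band, middle background) with distinct cell-type
#' compositions — compact, low-perimeter niches of the kind spatial bead
#' data shows, which keeps the k-nearest-bead community mixing confined
#' to the domain boundaries.
#'
#' `coloc_scenario()` scatters six circular domains with independently
#' drawn random compositions over a random background so that the five
#' cell-type abundance fields decorrelate, then (optionally) rewrites the
#' Treg field as `slope * Teff + noise` — the planted colocalization
#' pair.
#'
#' @param n_beads Number of beads (default 2000).
#' @param noise_sd Abundance noise SD (default 0.05).
#' @param seed Integer seed; both the geometry draws and the bead noise
#'   are pure functions of it.
#' @return A [spatial_sim_spec()].
#' @export
three_niche_scenario <- function(n_beads = 2000L, noise_sd = 0.05, seed = 0L) {
  spatial_sim_spec(
    n_beads = n_beads,
    niche_regions = list(
      list(center = c(-9.5, 0.5), radius = 9.5 + 1 / 3,
           composition = c(A = 0.45, B = 0.05, C = 0.10, D = 0.10)),
      list(center = c(10.5, 0.5), radius = 9.5 + 1 / 3,
           composition = c(A = 0.05, B = 0.45, C = 0.10, D = 0.10))),
    background_composition = c(A = 0.10, B = 0.10, C = 0.35, D = 0.15),
    noise_sd = noise_sd, seed = seed)
}

#' @rdname three_niche_scenario
#' @param coloc Plant the Teff->Treg pair (default TRUE); with `FALSE`
#'   the same landscape is generated without the dependence, giving the
#'   matched null (e.g. a healthy group).
#' @param slope Linear coefficient of the planted pair (default 1).
#' @param pair_noise_sd Noise SD on the dependent type (default 0.05).
#' @export
coloc_scenario <- function(n_beads = 2000L, noise_sd = 0.05, seed = 0L,
                           coloc = TRUE, slope = 1, pair_noise_sd = 0.05) {
  types <- c("Teff", "Treg", "Mac", "Epi", "Fib")
  # fixed landscape: each type is elevated in its own domain so the five
  # abundance fields decorrelate; only coords/noise vary with the seed
  comp <- rbind(c(0.50, 0.10, 0.10, 0.20, 0.10),
                c(0.10, 0.50, 0.20, 0.10, 0.10),
                c(0.10, 0.10, 0.50, 0.10, 0.20),
                c(0.20, 0.10, 0.10, 0.50, 0.10),
                c(0.10, 0.20, 0.10, 0.10, 0.50),
                c(0.40, 0.10, 0.30, 0.10, 0.10))
  centers <- rbind(c(0.2, 0.2), c(0.8, 0.2), c(0.5, 0.5),
                   c(0.2, 0.8), c(0.8, 0.8), c(0.5, 0.05))
  regions <- lapply(seq_len(6), function(i) {
    list(center = centers[i, ], radius = 0.2,
         composition = stats::setNames(comp[i, ], types))
  })
  background <- stats::setNames(rep(0.15, 5), types)
  pair <- if (coloc) {
    list(type_a = "Teff", type_b = "Treg", slope = slope,
         noise_sd = pair_noise_sd)
  }
  spatial_sim_spec(n_beads = n_beads, niche_regions = regions,
                   background_composition = background, noise_sd = noise_sd,
                   coloc_pair = pair, seed = seed)
}
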