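#' Assemble a synthetic scenario
#'
#' A scenario bundles a landscape, a set of clade regimes (one per cenocron
#' role), a presence threshold and a master seed, and is the unit the
#' simulator, the pipeline and the recovery tests operate on.
#'
#' @param landscape a [landscape_spec()].
#' @param clades list of [clade_regime()] objects with unique names; clade
#'   names double as cenocron labels downstream.
#' @param suitability_threshold presence cutoff in (0, 1).
#' @param stem_depth root depth of the simulated tree (Ma).
#' @param seed master integer seed; stage seeds are derived from it.
#' @return a `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(landscape, clades, suitability_threshold = 0.3,
                               stem_depth = NULL, seed = 1L) {
  stopifnot(inherits(landscape, "landscape_spec"))
  clades <- check_clades(clades)
  if (suitability_threshold <= 0 || suitability_threshold >= 1) {
    stop("`suitability_threshold` must lie in (0, 1)", call. = FALSE)
  }
  ages <- vapply(clades, `[[`, numeric(1), "crown_age")
  stem_depth <- stem_depth %||% (max(ages) * 1.25)
  structure(
    list(landscape = landscape, clades = clades,
         suitability_threshold = suitability_threshold,
         stem_depth = stem_depth, seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' The shipped default scenario
#'
#' A 50 x 50 landscape with a south-increasing temperature gradient, a
#' mountain-driven (conical) moisture and elevation field centred on the
#' grid, and a rough topographic noise layer. Three clades of 30 tips play
#' the cenocron roles: `Nearctic` (conserved, cold optimum at the northern
#' edge), `TypicalNeotropical` (conserved, warm-wet optimum at the southern
#' edge), and `MountainMesoamerican` (convergent: warm-dry ancestral optimum
#' displaced cold-wet at the clade stem, with narrow tolerances, so the clade
#' radiates on the mountain). Crown ages follow the relative dispersal
#' chronology of the cenocrons (oldest: mountain clade).
#'
#' @param seed master seed (default 2024).
#' @return a `synthetic_scenario`.
#' @export
default_scenario <- function(seed = 2024L) {
  land <- landscape_spec(
    n_rows = 50, n_cols = 50,
    layers = list(
      landscape_layer("temperature", "latitudinal-linear",
                      base = 10, range = 20, noise_sd = 0.4),
      landscape_layer("moisture", "elevational-conical",
                      base = 200, range = 800, noise_sd = 15, apex = c(25, 25)),
      landscape_layer("elevation", "elevational-conical",
                      base = 0, range = 3000, noise_sd = 40, apex = c(25, 25)),
      landscape_layer("roughness", "noise", base = 5, range = 0, noise_sd = 2)
    ),
    seed = seed
  )
  clades <- list(
    clade_regime(
      "Nearctic", "conserved", n_tips = 30, crown_age = 13,
      optimum = c(temperature = 12, moisture = 350),
      niche_sd = c(temperature = 3.5, moisture = 300),
      ou_strength = 3, ou_sigma = c(2, 60)
    ),
    clade_regime(
      "TypicalNeotropical", "conserved", n_tips = 30, crown_age = 5,
      optimum = c(temperature = 28, moisture = 700),
      niche_sd = c(temperature = 6, moisture = 320),
      ou_strength = 3, ou_sigma = c(2, 60)
    ),
    clade_regime(
      "MountainMesoamerican", "convergent", n_tips = 30, crown_age = 28,
      optimum = c(temperature = 27, moisture = 300),
      shift = c(temperature = -6, moisture = 450),
      niche_sd = c(temperature = 1, moisture = 120),
      ou_strength = 3, ou_sigma = c(1, 40)
    )
  )
  synthetic_scenario(land, clades, suitability_threshold = 0.3,
                     stem_depth = 40, seed = seed)
}

#' A scenario constructed for transition-zone recovery
#'
#' Noise-free landscape and very strong stabilizing pull (tip optima
#' essentially equal the clade optima), with the three clades' tolerances
#' arranged so their suitable environments jointly exceed the threshold only
#' inside a known envelope. The ground-truth co-suitability region is then
#' computable analytically with [co_suitability_mask()].
#'
#' @param seed master seed.
#' @return a `synthetic_scenario`.
#' @export
transition_scenario <- function(seed = 2024L) {
  land <- landscape_spec(
    n_rows = 50, n_cols = 50,
    layers = list(
      landscape_layer("temperature", "latitudinal-linear",
                      base = 10, range = 20, noise_sd = 0),
      landscape_layer("moisture", "elevational-conical",
                      base = 200, range = 800, noise_sd = 0, apex = c(25, 25))
    ),
    seed = seed
  )
  mk <- function(nm, t_opt, m_opt) {
    clade_regime(
      nm, "conserved", n_tips = 10, crown_age = 10,
      optimum = c(temperature = t_opt, moisture = m_opt),
      niche_sd = c(temperature = 5, moisture = 250),
      ou_strength = 50, ou_sigma = c(0.01, 0.01)
    )
  }
  clades <- list(
    mk("Nearctic", 16, 600),
    mk("TypicalNeotropical", 24, 700),
    mk("MountainMesoamerican", 20, 650)
  )
  synthetic_scenario(land, clades, suitability_threshold = 0.3,
                     stem_depth = 12, seed = seed)
}

#' Cells jointly suitable for every clade's own optimum
#'
#' Ground-truth mask for transition-zone recovery: a cell is marked when the
#' clade-level Gaussian-product suitability (evaluated at the clade optimum,
#' not at evolved tip optima) meets the scenario threshold for every clade.
#'
#' @param scenario a `synthetic_scenario`.
#' @param env optional pre-generated landscape (defaults to
#'   `generate_landscape(scenario$landscape)`).
#' @return a logical matrix.
#' @export
co_suitability_mask <- function(scenario, env = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  env <- env %||% generate_landscape(scenario$landscape)
  masks <- lapply(scenario$clades, function(cl) {
    suit <- matrix(1, env$n_rows, env$n_cols)
    for (v in names(cl$optimum)) {
      opt <- cl$optimum[[v]] + cl$shift[[v]]
      suit <- suit * exp(-(env[[v]] - opt)^2 / (2 * cl$niche_sd[[v]]^2))
    }
    suit >= scenario$suitability_threshold
  })
  Reduce(`&`, masks)
}

#' Run the synthetic generator end to end
#'
#' Generates the landscape, simulates the clade-structured phylogeny, evolves
#' niche optima, realizes binary ranges, and returns everything downstream
#' stages need, including the species-to-cenocron label table (clade names
#' are the cenocron labels).
#'
#' @param scenario a `synthetic_scenario`.
#' @return a list with elements `env` (grid_stack), `tree` (phylo), `niches`
#'   (tibble), `ranges` (grid_stack), `labels` (tibble `species`, `cenocron`),
#'   `scenario`.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  env <- generate_landscape(scenario$landscape)
  tree <- simulate_phylogeny(scenario$clades, scenario$stem_depth,
                             seed = scenario$seed + 1L)
  niches <- evolve_niches(tree, scenario$clades, scenario$stem_depth,
                          seed = scenario$seed + 2L)
  ranges <- realize_ranges(niches, env, scenario$suitability_threshold)
  labels <- dplyr::distinct(niches, .data$species, .data$clade)
  labels <- tibble::tibble(species = labels$species, cenocron = labels$clade)
  list(env = env, tree = tree, niches = niches, ranges = ranges,
       labels = labels, scenario = scenario)
}
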