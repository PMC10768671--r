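#' Realize binary ranges from niche optima and an environmental stack
#'
#' Suitability of a cell for a species is the product over environmental
#' variables of independent Gaussian kernels,
#' `prod_v exp(-(env_v - optimum_v)^2 / (2 sd_v^2))`; the species is present
#' wherever suitability meets the threshold. Species whose realized range is
#' empty are kept (all-zero layer) and reported with a warning, so
#' range-size-weighted metrics can apply their own guard.
#'
#' @param niche_table long tibble from [evolve_niches()] (columns `species`,
#'   `variable`, `optimum`, `sd`).
#' @param env a `grid_stack` of environmental layers; must contain every
#'   variable in `niche_table`.
#' @param suitability_threshold presence cutoff in (0, 1).
#' @return a `grid_stack` of kind `"range"`, one 0/1 layer per species.
#' @export
realize_ranges <- function(niche_table, env, suitability_threshold = 0.3) {
  stopifnot(inherits(env, "grid_stack"))
  if (suitability_threshold <= 0 || suitability_threshold >= 1) {
    stop("`suitability_threshold` must lie in (0, 1)", call. = FALSE)
  }
  vars <- unique(niche_table$variable)
  missing <- setdiff(vars, names(env))
  if (length(missing) > 0) {
    stop("environmental layer(s) missing for variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  by_species <- split(niche_table, niche_table$species)
  layers <- lapply(by_species, function(nt) {
    suit <- matrix(1, env$n_rows, env$n_cols)
    for (i in seq_len(nrow(nt))) {
      e <- env[[nt$variable[i]]]
      suit <- suit * exp(-(e - nt$optimum[i])^2 / (2 * nt$sd[i]^2))
    }
    (suit >= suitability_threshold) * 1L
  })
  sizes <- vapply(layers, sum, numeric(1))
  if (any(sizes == 0)) {
    warning("species with empty realized ranges: ",
            paste(names(layers)[sizes == 0], collapse = ", "), call. = FALSE)
  }
  grid_stack(layers, kind = "range")
}

#' Range size (occupied cells) per species
#'
#' @param ranges a range `grid_stack`.
#' @return a tibble with columns `species`, `range_size`.
#' @export
range_sizes <- function(ranges) {
  stopifnot(inherits(ranges, "grid_stack"))
  tibble::tibble(
    species = names(ranges),
    range_size = vapply(ranges$layers, sum, numeric(1))
  )
}
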