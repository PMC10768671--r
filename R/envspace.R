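#' Principal component analysis of the environmental layers
#'
#' Correlation-matrix PCA of the valid (non-`NA` in every layer) cells:
#' variables are standardized to zero mean and unit sd, components ordered by
#' decreasing variance, and each component's sign fixed so its
#' largest-magnitude loading is positive. Per-cell scores are computed for
#' the retained components.
#'
#' @param env a `grid_stack` with at least 2 layers and 3 valid cells.
#' @param n_components components to retain (default 2).
#' @param bin_width width of the square score bins used for occupancy and
#'   overlap detection, in score units (default 0.1).
#' @return a `pc_space` object: `variables`, `loadings`, `center`, `scale`,
#'   `prop_var` (all components), `scores` (list of score matrices on the
#'   grid, one per retained component), `bin_width`, `valid` mask.
#' @export
fit_pca <- function(env, n_components = 2, bin_width = 0.1) {
  stopifnot(inherits(env, "grid_stack"))
  if (length(env) < 2) stop("at least 2 layers are required", call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)
  X <- vapply(env$layers, as.vector, numeric(env$n_rows * env$n_cols))
  valid <- stats::complete.cases(X)
  if (sum(valid) < 3) stop("fewer than 3 valid cells", call. = FALSE)
  sds <- apply(X[valid, , drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant layer(s): ", paste(names(env)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::prcomp(X[valid, , drop = FALSE], center = TRUE, scale. = TRUE)
  # sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  prop_var <- fit$sdev^2 / sum(fit$sdev^2)
  n_components <- min(n_components, ncol(fit$rotation))
  scores <- lapply(seq_len(n_components), function(j) {
    m <- matrix(NA_real_, env$n_rows, env$n_cols)
    m[valid] <- fit$x[, j]
    m
  })
  names(scores) <- paste0("PC", seq_len(n_components))
  structure(
    list(variables = names(env), loadings = fit$rotation,
         center = fit$center, scale = fit$scale,
         prop_var = stats::setNames(prop_var, colnames(fit$rotation)),
         scores = scores, bin_width = bin_width,
         valid = matrix(valid, env$n_rows, env$n_cols)),
    class = "pc_space"
  )
}

#' @export
print.pc_space <- function(x, ...) {
  cat(sprintf("<pc_space> %d variables, %d retained component(s), bin width %.3g\n",
              length(x$variables), length(x$scores), x$bin_width))
  pv <- x$prop_var[seq_along(x$scores)]
  cat("variance explained:",
      paste(sprintf("%s %.1f%%", names(pv), 100 * pv), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.pc_space <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.pc_space <- function(x, ...) {
  tibble::tibble(
    component = names(x$prop_var),
    prop_var = unname(x$prop_var),
    cum_prop = cumsum(unname(x$prop_var))
  )
}

score_bins <- function(pcspace) {
  lapply(pcspace$scores, function(s) floor(s / pcspace$bin_width))
}

#' Environmental-space occupancy per species
#'
#' A species occupies every score bin that contains at least one of its
#' presence cells (bin index = `floor(score / bin_width)` per retained
#' component); cells with identical binned environments collapse to one bin.
#'
#' @param ranges a range `grid_stack`, co-registered with the PCA grid.
#' @param pcspace a `pc_space` from [fit_pca()].
#' @return a tibble `species`, `bin1`, `bin2`, ... (one row per occupied
#'   bin per species). Species with empty ranges have no rows.
#' @export
project_species <- function(ranges, pcspace) {
  stopifnot(inherits(ranges, "grid_stack"), inherits(pcspace, "pc_space"))
  stopifnot_shared_geometry(ranges, pcspace$valid, "ranges and PCA scores")
  bins <- score_bins(pcspace)
  purrr::map_dfr(names(ranges), function(sp) {
    present <- ranges[[sp]] == 1 & pcspace$valid
    if (!any(present)) return(tibble::tibble())
    b <- vapply(bins, function(bm) bm[present], numeric(sum(present)))
    if (sum(present) == 1L) b <- matrix(b, nrow = 1)
    colnames(b) <- paste0("bin", seq_along(bins))
    dplyr::distinct(dplyr::bind_cols(tibble::tibble(species = sp),
                                     tibble::as_tibble(b)))
  })
}

bin_key <- function(df) {
  bincols <- grep("^bin", names(df), value = TRUE)
  do.call(paste, c(df[bincols], sep = ","))
}

#' Species density per environmental-space bin and cenocron
#'
#' Density of a bin for a cenocron = number of that cenocron's species
#' occupying the bin divided by the cenocron's species count (so it lies in
#' `[0, 1]`). Unoccupied bins are simply absent (density 0).
#'
#' @param occupancies tibble from [project_species()].
#' @param labels tibble `species`, `cenocron`.
#' @return tibble `cenocron`, `bin1`, `bin2`, ..., `n_species`, `density`.
#' @export
env_density <- function(occupancies, labels) {
  labels <- tibble::as_tibble(labels)
  occ <- dplyr::left_join(occupancies, labels, by = "species")
  if (anyNA(occ$cenocron)) {
    warning("species without a label assigned to the Unassigned stratum",
            call. = FALSE)
    occ$cenocron[is.na(occ$cenocron)] <- "Unassigned"
  }
  sizes <- dplyr::count(
    dplyr::distinct(occ, .data$species, .data$cenocron),
    .data$cenocron, name = "n_total"
  )
  if (any(sizes$n_total == 0)) stop("cenocron with zero species", call. = FALSE)
  bincols <- grep("^bin", names(occupancies), value = TRUE)
  occ |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c("species", "cenocron", bincols)))) |>
    dplyr::count(dplyr::across(dplyr::all_of(c("cenocron", bincols))),
                 name = "n_species") |>
    dplyr::left_join(sizes, by = "cenocron") |>
    dplyr::mutate(density = .data$n_species / .data$n_total) |>
    dplyr::select(-"n_total")
}

#' Environmental transition zone: bins occupied by every required cenocron
#'
#' @param occupancies tibble from [project_species()].
#' @param labels tibble `species`, `cenocron`.
#' @param required cenocron labels that must all be present in a bin
#'   (default: every label observed in `labels`).
#' @return a `transition_zone` object: tibble of zone bins (`bin1`, `bin2`,
#'   ...) with the `required` set and bin width recorded as attributes.
#' @export
overlap_zone <- function(occupancies, labels, required = NULL) {
  labels <- tibble::as_tibble(labels)
  required <- required %||% sort(unique(labels$cenocron))
  missing <- setdiff(required, unique(labels$cenocron))
  if (length(missing) > 0) {
    stop("required cenocron(s) not in labels: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  occ <- dplyr::inner_join(occupancies, labels, by = "species")
  bincols <- grep("^bin", names(occupancies), value = TRUE)
  zone <- occ |>
    dplyr::filter(.data$cenocron %in% required) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c("cenocron", bincols)))) |>
    dplyr::count(dplyr::across(dplyr::all_of(bincols)), name = "n_cenocrons") |>
    dplyr::filter(.data$n_cenocrons == length(unique(required))) |>
    dplyr::select(-"n_cenocrons")
  structure(zone, class = c("transition_zone", class(zone)),
            required = required)
}

#' Back-project an environmental transition zone to geography
#'
#' A cell is masked when its binned scores fall in the zone's bin set;
#' nodata cells are never masked.
#'
#' @param zone a `transition_zone` from [overlap_zone()].
#' @param pcspace the `pc_space` the zone's bins were defined on.
#' @return a logical matrix on the score grid.
#' @export
back_project <- function(zone, pcspace) {
  stopifnot(inherits(pcspace, "pc_space"))
  bins <- score_bins(pcspace)
  if (nrow(zone) == 0) {
    return(matrix(FALSE, nrow(pcspace$valid), ncol(pcspace$valid)))
  }
  cellkey <- do.call(paste, c(lapply(bins, as.vector), sep = ","))
  zonekey <- bin_key(tibble::as_tibble(zone))
  matrix(cellkey %in% zonekey, nrow(pcspace$valid), ncol(pcspace$valid)) &
    pcspace$valid
}

#' Scatter plot of environmental-space density per cenocron
#'
#' @param density tibble from [env_density()].
#' @param pcspace the `pc_space` (for axis scaling).
#' @return a ggplot object (one panel per cenocron, tiles at bin centres).
#' @export
plot_env_density <- function(density, pcspace) {
  bw <- pcspace$bin_width
  ggplot2::ggplot(density, ggplot2::aes(
    x = (.data$bin1 + 0.5) * bw, y = (.data$bin2 + 0.5) * bw,
    fill = .data$density
  )) +
    ggplot2::geom_tile(width = bw, height = bw) +
    ggplot2::facet_wrap(~cenocron) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "PC1", y = "PC2", fill = "density")
}
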