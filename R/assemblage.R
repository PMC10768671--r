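#' Per-cell species richness from stacked binary ranges
#'
#' @param ranges a range `grid_stack`.
#' @return an integer matrix (sum of the binary layers).
#' @export
stack_richness <- function(ranges) {
  stopifnot(inherits(ranges, "grid_stack"))
  if (length(ranges) == 0) stop("empty RangeSet", call. = FALSE)
  Reduce(`+`, ranges$layers)
}

#' Sample site cells uniformly without replacement
#'
#' @param geometry a `grid_stack` (or anything with `dim()` of length 2)
#'   defining the grid.
#' @param n_sites number of cells to draw.
#' @param seed integer seed.
#' @param mask optional logical matrix; only `TRUE` (valid) cells are
#'   eligible. Default: all cells.
#' @return a tibble `site`, `row`, `col` ordered by site id.
#' @export
sample_sites <- function(geometry, n_sites, seed = 1L, mask = NULL) {
  d <- dim(geometry)
  valid <- if (is.null(mask)) rep(TRUE, prod(d)) else as.vector(mask)
  idx <- which(valid)
  if (n_sites > length(idx)) {
    stop(sprintf("n_sites (%d) exceeds the %d valid cells", n_sites, length(idx)),
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  chosen <- sort(sample(idx, n_sites, replace = FALSE))
  tibble::tibble(
    site = seq_along(chosen),
    row = ((chosen - 1L) %% d[1]) + 1L,
    col = ((chosen - 1L) %/% d[1]) + 1L
  )
}

#' Build a sites-by-species community matrix
#'
#' Species absent from every sampled site are kept as all-zero columns.
#'
#' @param ranges a range `grid_stack`.
#' @param sites tibble from [sample_sites()] (columns `site`, `row`, `col`).
#' @return a binary matrix, `nrow(sites)` x `length(ranges)`, with
#'   dimnames (site ids, species); class `community_matrix` with the sites
#'   tibble attached as attribute `sites`.
#' @export
build_community_matrix <- function(ranges, sites) {
  stopifnot(inherits(ranges, "grid_stack"))
  cell <- cbind(sites$row, sites$col)
  m <- vapply(ranges$layers, function(r) r[cell], numeric(nrow(cell)))
  if (nrow(cell) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(ranges)))
  rownames(m) <- as.character(sites$site)
  structure(m, class = c("community_matrix", class(m)), sites = sites)
}

check_species_on_tree <- function(species, tree) {
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0) {
    stop("species missing from the tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Pendant (terminal) branch length per tip
#'
#' @param tree an [ape::phylo] tree.
#' @return named numeric vector over tips.
#' @export
pendant_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  tip_edge <- match(seq_len(ntip), tree$edge[, 2])
  stats::setNames(tree$edge.length[tip_edge], tree$tip.label)
}

#' Number of internal nodes on each tip's root path (root included)
#'
#' @param tree an [ape::phylo] tree.
#' @return named integer vector over tips.
#' @export
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  depths <- vapply(seq_len(ntip), function(tip) {
    d <- 0L
    node <- tip
    while (node != root) {
      node <- parent[node]
      d <- d + 1L
    }
    d
  }, integer(1))
  stats::setNames(depths, tree$tip.label)
}

per_cell_mean <- function(ranges, values) {
  richness <- stack_richness(ranges)
  acc <- matrix(0, ranges$n_rows, ranges$n_cols)
  for (sp in names(ranges)) {
    acc <- acc + ranges[[sp]] * values[[sp]]
  }
  out <- acc / richness
  out[richness == 0] <- NA_real_
  out
}

#' Mean pendant branch length ("age", Ma) of the species in each cell
#'
#' @param ranges a range `grid_stack`.
#' @param tree a dated [ape::phylo] tree containing every range species.
#' @return a numeric matrix; `NA` (nodata) where richness is 0.
#' @export
mean_tip_age <- function(ranges, tree) {
  check_species_on_tree(names(ranges), tree)
  per_cell_mean(ranges, pendant_lengths(tree))
}

#' Mean tip-to-root node count of the species in each cell
#'
#' @inheritParams mean_tip_age
#' @return a numeric matrix; `NA` where richness is 0.
#' @export
mean_node_depth <- function(ranges, tree) {
  check_species_on_tree(names(ranges), tree)
  per_cell_mean(ranges, node_depths(tree))
}

# Edge-by-tip incidence: M[e, t] = 1 when edge e lies on tip t's root path.
edge_tip_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  parent <- integer(max(tree$edge))
  edge_to <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_to[tree$edge[, 2]] <- seq_len(nedge)
  root <- ntip + 1L
  M <- matrix(0, nedge, ntip, dimnames = list(NULL, tree$tip.label))
  for (tip in seq_len(ntip)) {
    node <- tip
    while (node != root) {
      M[edge_to[node], tip] <- 1
      node <- parent[node]
    }
  }
  M
}

#' Faith's phylogenetic diversity per site
#'
#' PD of a site is the sum of branch lengths of the subtree spanning the
#' site's species and the tree root (the root path is included, so a
#' single-species site returns its full tip-to-root path length). Empty
#' sites return `NA`.
#'
#' @param community a binary sites-by-species matrix (e.g. from
#'   [build_community_matrix()]).
#' @param tree an [ape::phylo] tree containing every community species.
#' @return numeric vector of PD values, one per site (row).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' cm <- rbind(site1 = c(A = 1, B = 1, C = 0), site2 = c(A = 0, B = 0, C = 1))
#' faith_pd(cm, tr)  # 3, 2
faith_pd <- function(community, tree) {
  community <- as.matrix(community)
  check_species_on_tree(colnames(community), tree)
  M <- edge_tip_incidence(tree)[, colnames(community), drop = FALSE]
  used <- M %*% t(community) > 0          # edges x sites
  pd <- as.vector(crossprod(used, tree$edge.length))
  pd[rowSums(community) == 0] <- NA_real_
  stats::setNames(pd, rownames(community))
}

#' Standardized effect size of PD under the tip-shuffle null
#'
#' Tip labels are permuted over the fixed tree topology `n_rand` times and PD
#' recomputed for every site; `SES = (observed - null mean) / null sd`. Sites
#' where the null sd is 0 (e.g. a site containing all tips, whose PD is
#' invariant under relabeling) get SES 0. Empty sites return `NA`.
#'
#' @inheritParams faith_pd
#' @param n_rand number of randomizations (>= 2; default 999).
#' @param seed integer seed.
#' @return a tibble `site`, `pd_obs`, `null_mean`, `null_sd`, `ses`.
#' @export
tip_shuffle_ses <- function(community, tree, n_rand = 999, seed = 1L) {
  if (n_rand < 2) stop("`n_rand` must be >= 2", call. = FALSE)
  community <- as.matrix(community)
  check_species_on_tree(colnames(community), tree)
  M <- edge_tip_incidence(tree)
  tips <- colnames(M)
  common <- intersect(tips, colnames(community))
  # tips-by-sites presence, aligned to tree tip order; tree tips absent from
  # the community are never present
  P_full <- matrix(0, length(tips), nrow(community),
                   dimnames = list(tips, rownames(community)))
  P_full[common, ] <- t(community[, common, drop = FALSE])
  obs <- as.vector(crossprod(M %*% P_full > 0, tree$edge.length))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nulls <- matrix(NA_real_, nrow(community), n_rand)
  for (k in seq_len(n_rand)) {
    perm <- sample.int(length(tips))
    nulls[, k] <- as.vector(crossprod(M[, perm, drop = FALSE] %*% P_full > 0,
                                      tree$edge.length))
  }
  null_mean <- rowMeans(nulls)
  null_sd <- apply(nulls, 1, stats::sd)
  ses <- (obs - null_mean) / null_sd
  ses[null_sd == 0] <- 0
  empty <- rowSums(community) == 0
  obs[empty] <- NA_real_
  ses[empty] <- NA_real_
  tibble::tibble(
    site = rownames(community) %||% as.character(seq_len(nrow(community))),
    pd_obs = obs, null_mean = null_mean, null_sd = null_sd, ses = ses
  )
}

#' Weighted endemism surface
#'
#' Each present species contributes the reciprocal of its range size (in
#' cells, over the full analysis extent) to every cell it occupies; empty
#' species contribute nowhere. The grid total therefore equals the number of
#' species with non-empty ranges.
#'
#' @param ranges a range `grid_stack`.
#' @return a numeric matrix (0 where no species occurs).
#' @export
weighted_endemism <- function(ranges) {
  stopifnot(inherits(ranges, "grid_stack"))
  acc <- matrix(0, ranges$n_rows, ranges$n_cols)
  for (sp in names(ranges)) {
    size <- sum(ranges[[sp]])
    if (size > 0) acc <- acc + ranges[[sp]] / size
  }
  acc
}

#' Compute all assemblage metrics, stratified by cenocron
#'
#' Runs the full metric set on the total species pool and on every cenocron
#' stratum separately. Per-stratum runs subset the ranges, recompute range
#' sizes within the stratum, and prune the tree to the stratum's species.
#' Per-cell metrics (richness, age, node depth, weighted endemism) are
#' computed on the full grid; PD and its tip-shuffle SES on a sampled
#' community matrix. Strata with fewer than 2 species skip SES with a
#' warning.
#'
#' @param ranges a range `grid_stack`.
#' @param tree dated [ape::phylo] tree covering all species.
#' @param labels tibble `species`, `cenocron`; species missing from it join
#'   an `Unassigned` stratum.
#' @param n_sites number of sites to sample for the community matrix.
#' @param n_rand tip-shuffle randomizations (default 999).
#' @param seed integer seed (site sampling and null model).
#' @return an `assemblage_result`: list with `sites`, `strata` (named list;
#'   each stratum has `species`, `grids` (a grid_stack of richness, mean_age,
#'   mean_nodes, weighted_endemism), `site_metrics` tibble with per-site
#'   metric values incl. `pd` and `ses_pd`), and `params`.
#' @export
compute_assemblage <- function(ranges, tree, labels, n_sites = 2000,
                               n_rand = 999, seed = 1L) {
  stopifnot(inherits(ranges, "grid_stack"))
  check_species_on_tree(names(ranges), tree)
  labels <- tibble::as_tibble(labels)
  lab <- stats::setNames(labels$cenocron, labels$species)[names(ranges)]
  lab[is.na(lab)] <- "Unassigned"
  sites <- sample_sites(ranges, n_sites, seed = seed)
  strata <- c(list(total = names(ranges)),
              split(names(ranges), lab))
  cell <- cbind(sites$row, sites$col)
  out <- purrr::imap(strata, function(spp, stratum) {
    sub_ranges <- grid_stack(ranges$layers[spp], kind = "range")
    sub_tree <- if (length(spp) < length(tree$tip.label)) {
      ape::keep.tip(tree, spp)
    } else {
      tree
    }
    richness <- stack_richness(sub_ranges)
    grids <- grid_stack(list(
      richness = richness,
      mean_age = mean_tip_age(sub_ranges, sub_tree),
      mean_nodes = mean_node_depth(sub_ranges, sub_tree),
      weighted_endemism = weighted_endemism(sub_ranges)
    ), kind = "metric")
    cm <- build_community_matrix(sub_ranges, sites)
    pd <- faith_pd(cm, sub_tree)
    ses <- if (length(spp) >= 2) {
      tip_shuffle_ses(cm, sub_tree, n_rand = n_rand, seed = seed + 1L)$ses
    } else {
      warning("stratum '", stratum, "' has < 2 species; SES skipped",
              call. = FALSE)
      rep(NA_real_, nrow(cm))
    }
    site_metrics <- tibble::tibble(
      site = sites$site, row = sites$row, col = sites$col,
      richness = richness[cell],
      mean_age = grids[["mean_age"]][cell],
      mean_nodes = grids[["mean_nodes"]][cell],
      weighted_endemism = grids[["weighted_endemism"]][cell],
      pd = unname(pd), ses_pd = ses
    )
    list(species = spp, grids = grids, community = cm,
         site_metrics = site_metrics)
  })
  structure(
    list(sites = sites, strata = out,
         params = list(n_sites = n_sites, n_rand = n_rand, seed = seed)),
    class = "assemblage_result"
  )
}

#' @export
print.assemblage_result <- function(x, ...) {
  cat(sprintf(
    "<assemblage_result> %d strata (%s); %d sites, %d tip-shuffle randomizations\n",
    length(x$strata), paste(names(x$strata), collapse = ", "),
    nrow(x$sites), x$params$n_rand
  ))
  invisible(x)
}

#' Long per-site metric table across strata
#'
#' @param x an `assemblage_result`.
#' @param ... unused.
#' @return tibble with columns `cenocron`, `site`, `row`, `col`, `metric`,
#'   `value`.
#' @export
tidy.assemblage_result <- function(x, ...) {
  purrr::imap_dfr(x$strata, function(st, nm) {
    tidyr::pivot_longer(st$site_metrics,
                        cols = c("richness", "mean_age", "mean_nodes",
                                 "weighted_endemism", "pd", "ses_pd"),
                        names_to = "metric", values_to = "value") |>
      dplyr::mutate(cenocron = nm, .before = 1)
  })
}

#' One-row-per-stratum summary of an assemblage result
#'
#' @param x an `assemblage_result`.
#' @param ... unused.
#' @return tibble with stratum-level means of the metrics.
#' @export
glance.assemblage_result <- function(x, ...) {
  purrr::imap_dfr(x$strata, function(st, nm) {
    sm <- st$site_metrics
    tibble::tibble(
      cenocron = nm,
      n_species = length(st$species),
      mean_richness = mean(sm$richness),
      mean_age = mean(sm$mean_age, na.rm = TRUE),
      mean_nodes = mean(sm$mean_nodes, na.rm = TRUE),
      mean_we = mean(sm$weighted_endemism),
      mean_pd = mean(sm$pd, na.rm = TRUE),
      mean_ses_pd = mean(sm$ses_pd, na.rm = TRUE)
    )
  })
}

#' Map panels of one stratum's metric surfaces
#'
#' @param result an `assemblage_result`.
#' @param stratum stratum name (default `"total"`).
#' @return a ggplot object.
#' @export
plot_assemblage <- function(result, stratum = "total") {
  autoplot(result$strata[[stratum]]$grids)
}
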