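#' Default region-to-macroregion mapping
#'
#' Biogeographic regions/realms are recoded into three macro-regions:
#' northern hemisphere (Nearctic, Palearctic, Saharo-Arabian), southern
#' hemisphere (Afrotropics, Neotropics), and Mesoamerican (Mexican Transition
#' Zone, Mesoamerican dominion).
#'
#' @return a tibble with columns `region`, `macro_region`.
#' @export
region_mapping <- function() {
  tibble::tribble(
    ~region,                   ~macro_region,
    "Nearctic",                "northern",
    "Palearctic",              "northern",
    "Saharo-Arabian",          "northern",
    "Afrotropics",             "southern",
    "Neotropics",              "southern",
    "Mexican Transition Zone", "mesoamerican",
    "Mesoamerican dominion",   "mesoamerican"
  )
}

#' Tally species per macro-region for each family
#'
#' Recodes per-species region records into the three macro-regions and counts
#' species per family. The phylogenetic affinity of related species
#' (`related_affinity`) is an expert-supplied per-family input, not computed
#' here; it may travel as a column of `species_table` (constant within
#' family) or in a separate `affinities` table.
#'
#' @param species_table tibble/data frame with columns `species`, `family`,
#'   `region`, and optionally `related_affinity`.
#' @param mapping region mapping (default [region_mapping()]); extra rows may
#'   be supplied to extend it.
#' @param affinities optional tibble with columns `family`,
#'   `related_affinity` in `{northern, neotropical, unknown}`.
#' @return a tibble with one row per family: `family`, `n_northern`,
#'   `n_southern`, `n_mesoamerican`, `related_affinity`.
#' @export
recode_regions <- function(species_table, mapping = region_mapping(),
                           affinities = NULL) {
  need <- c("species", "family", "region")
  if (!all(need %in% names(species_table))) {
    stop("`species_table` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unmapped <- setdiff(unique(species_table$region), mapping$region)
  if (length(unmapped) > 0) {
    stop("unmapped region value(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::left_join(tibble::as_tibble(species_table), mapping, by = "region")
  tallies <- df |>
    dplyr::count(.data$family, .data$macro_region) |>
    tidyr::pivot_wider(names_from = "macro_region", values_from = "n",
                       values_fill = 0L)
  for (col in c("northern", "southern", "mesoamerican")) {
    if (!col %in% names(tallies)) tallies[[col]] <- 0L
  }
  tallies <- dplyr::rename(tallies, n_northern = "northern",
                           n_southern = "southern",
                           n_mesoamerican = "mesoamerican")
  aff <- if (!is.null(affinities)) {
    tibble::as_tibble(affinities)[, c("family", "related_affinity")]
  } else if ("related_affinity" %in% names(species_table)) {
    dplyr::distinct(df, .data$family, .data$related_affinity)
  } else {
    tibble::tibble(family = unique(df$family), related_affinity = "unknown")
  }
  if (anyDuplicated(aff$family)) {
    stop("`related_affinity` must be constant within family", call. = FALSE)
  }
  out <- dplyr::left_join(tallies, aff, by = "family")
  out$related_affinity[is.na(out$related_affinity)] <- "unknown"
  dplyr::select(out, "family", "n_northern", "n_southern", "n_mesoamerican",
                "related_affinity") |>
    dplyr::arrange(.data$family)
}

#' Classify families into cenocrons by the three distributional rules
#'
#' Rules are evaluated in fixed order, first match wins:
#' 1. **Nearctic** — more than 80% of the family's species occur in the
#'    northern hemisphere (sufficient on its own), *or* the family has
#'    strictly more northern species than southern and than Mesoamerican
#'    species and its phylogenetically related species are Nearctic
#'    (northern affinity).
#' 2. **MountainMesoamerican** — strictly more Mesoamerican species than
#'    northern and than southern, and related species are Neotropical.
#' 3. **TypicalNeotropical** — more than 80% of species in the southern
#'    hemisphere, and related species are Neotropical.
#'
#' Families matching no rule are `Unassigned` (the rules are neither
#' exhaustive nor mutually exclusive). Shares use strict `>` at 0.8.
#'
#' @param tallies tibble from [recode_regions()] (columns `family`,
#'   `n_northern`, `n_southern`, `n_mesoamerican`, `related_affinity`), or a
#'   single-row equivalent.
#' @return the input tibble with columns `cenocron` and `rule_fired` added.
#' @export
#' @examples
#' classify_family(tibble::tibble(
#'   family = "F1", n_northern = 9, n_southern = 1, n_mesoamerican = 0,
#'   related_affinity = "northern"
#' ))
classify_family <- function(tallies) {
  t <- tibble::as_tibble(tallies)
  need <- c("n_northern", "n_southern", "n_mesoamerican", "related_affinity")
  if (!all(need %in% names(t))) {
    stop("tallies need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  total <- t$n_northern + t$n_southern + t$n_mesoamerican
  if (any(total <= 0)) stop("zero-total tally (no species counted)", call. = FALSE)
  if (any(c(t$n_northern, t$n_southern, t$n_mesoamerican) < 0)) {
    stop("negative counts are invalid", call. = FALSE)
  }
  share_n <- t$n_northern / total
  share_s <- t$n_southern / total
  aff <- t$related_affinity

  r1_share <- share_n > 0.8
  r1_major <- t$n_northern > t$n_southern & t$n_northern > t$n_mesoamerican &
    aff == "northern"
  r2 <- t$n_mesoamerican > t$n_southern & t$n_mesoamerican > t$n_northern &
    aff == "neotropical"
  r3 <- share_s > 0.8 & aff == "neotropical"

  cenocron <- rep("Unassigned", nrow(t))
  rule_fired <- rep("none", nrow(t))
  hit3 <- r3
  cenocron[hit3] <- "TypicalNeotropical"
  rule_fired[hit3] <- "rule 3: >80% southern & neotropical relatives"
  hit2 <- r2
  cenocron[hit2] <- "MountainMesoamerican"
  rule_fired[hit2] <- "rule 2: mesoamerican majority & neotropical relatives"
  hit1 <- r1_share | r1_major
  cenocron[hit1] <- "Nearctic"
  rule_fired[hit1] <- ifelse(r1_share[hit1],
                             "rule 1: >80% northern",
                             "rule 1: northern majority & nearctic relatives")
  t$cenocron <- cenocron
  t$rule_fired <- rule_fired
  t
}

#' Classify every family and summarise label counts
#'
#' @param tallies tibble from [recode_regions()]; family names must be unique.
#' @return a `cenocron_classification` object: the labeled tibble with a
#'   summary attribute. `tidy()` returns the table, `glance()` the per-label
#'   counts.
#' @export
classify_all <- function(tallies) {
  t <- tibble::as_tibble(tallies)
  if (nrow(t) == 0) stop("at least one tally is required", call. = FALSE)
  if (anyDuplicated(t$family)) {
    stop("duplicated family names: ",
         paste(unique(t$family[duplicated(t$family)]), collapse = ", "),
         call. = FALSE)
  }
  labeled <- classify_family(t)
  unassigned <- labeled$family[labeled$cenocron == "Unassigned"]
  if (length(unassigned) > 0) {
    warning("families left Unassigned (no rule fired): ",
            paste(unassigned, collapse = ", "), call. = FALSE)
  }
  structure(labeled, class = c("cenocron_classification", class(labeled)),
            unassigned = unassigned)
}

#' @export
tidy.cenocron_classification <- function(x, ...) {
  tibble::as_tibble(unclass_keep(x))
}

#' @export
glance.cenocron_classification <- function(x, ...) {
  tb <- tibble::as_tibble(unclass_keep(x))
  dplyr::count(tb, .data$cenocron, name = "n_families") |>
    tidyr::pivot_wider(names_from = "cenocron", values_from = "n_families",
                       values_fill = 0L)
}

unclass_keep <- function(x) {
  class(x) <- setdiff(class(x), "cenocron_classification")
  x
}

#' Propagate family labels to species
#'
#' @param species_table tibble with columns `species`, `family`.
#' @param classification result of [classify_all()].
#' @return tibble `species`, `family`, `cenocron`.
#' @export
species_labels <- function(species_table, classification) {
  dplyr::left_join(
    tibble::as_tibble(species_table)[, c("species", "family")],
    tibble::as_tibble(unclass_keep(classification))[, c("family", "cenocron")],
    by = "family"
  )
}

#' Bar plot of family counts per cenocron
#'
#' @param classification result of [classify_all()].
#' @return a ggplot object.
#' @export
plot_cenocron_counts <- function(classification) {
  tb <- tibble::as_tibble(unclass_keep(classification))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$cenocron)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "families")
}
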