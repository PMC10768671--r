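#' Configure a pipeline run
#'
#' Either a `scenario` (simulate inputs) or the four input paths (`ranges`,
#' `tree`, `env`, `labels`) must be supplied.
#'
#' @param output_dir directory the run writes into (created if needed).
#' @param scenario optional `synthetic_scenario` to simulate inputs from.
#' @param ranges,tree,env,labels input file paths (ignored when `scenario`
#'   is given).
#' @param n_sites community-matrix sites (default 2000).
#' @param n_rand tip-shuffle randomizations (default 999).
#' @param bin_width environmental-space bin width (default 0.1).
#' @param n_components retained principal components (default 2).
#' @param alpha significance level (default 0.05).
#' @param threshold_high,threshold_low verdict cutoffs on mean |r|.
#' @param verdict_metrics metric(s) the verdict uses.
#' @param predictions optional tibble `cenocron`, `variable`,
#'   `expected_sign`.
#' @param seed master seed.
#' @return a `run_config` list (validated).
#' @export
run_config <- function(output_dir, scenario = NULL, ranges = NULL, tree = NULL,
                       env = NULL, labels = NULL, n_sites = 2000, n_rand = 999,
                       bin_width = 0.1, n_components = 2, alpha = 0.05,
                       threshold_high = 0.5, threshold_low = 0.3,
                       verdict_metrics = "richness", predictions = NULL,
                       seed = 1L) {
  if (is.null(scenario)) {
    paths <- list(ranges = ranges, tree = tree, env = env, labels = labels)
    missing <- names(paths)[vapply(paths, is.null, logical(1))]
    if (length(missing) > 0) {
      stop("without a scenario, input path(s) required: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent) > 0) {
      stop("input file(s) not found: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  } else {
    stopifnot(inherits(scenario, "synthetic_scenario"))
  }
  if (n_sites < 1 || n_rand < 2) stop("counts must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)
  structure(
    list(output_dir = output_dir, scenario = scenario,
         paths = list(ranges = ranges, tree = tree, env = env, labels = labels),
         n_sites = n_sites, n_rand = n_rand, bin_width = bin_width,
         n_components = n_components, alpha = alpha,
         threshold_high = threshold_high, threshold_low = threshold_low,
         verdict_metrics = verdict_metrics, predictions = predictions,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

write_csv_plain <- function(df, path) {
  readr::write_csv(tibble::as_tibble(df), path)
  path
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Stages: simulate (optional) -> assemblage -> environmental space ->
#' diagnostics. Writes all outputs (grids as text grid-stacks, tables as
#' CSV) plus a JSON manifest recording parameters, seeds and per-file
#' checksums. Reruns with the same config reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all in-memory stage results and
#'   `output_dir`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  outd <- config$output_dir

  say("stage: inputs")
  sim <- if (!is.null(config$scenario)) {
    stage("simulate", simulate_scenario(config$scenario))
  } else {
    stage("read", {
      ranges <- read_ranges(config$paths$ranges)
      tree <- read_tree(config$paths$tree)
      rec <- reconcile_names(tree, ranges)
      if (length(rec$species_without_tip) > 0) {
        stop("range species missing from tree: ",
             paste(rec$species_without_tip, collapse = ", "))
      }
      list(env = read_env(config$paths$env), tree = rec$tree,
           ranges = rec$ranges, labels = read_labels(config$paths$labels),
           niches = NULL, scenario = NULL)
    })
  }
  stopifnot_shared_geometry(sim$ranges, sim$env, "ranges and environment")
  write_grid_stack(sim$ranges, file.path(outd, "ranges.grid"))
  write_grid_stack(sim$env, file.path(outd, "environment.grid"))
  ape::write.tree(sim$tree, file.path(outd, "tree.nwk"))
  write_csv_plain(sim$labels, file.path(outd, "labels.csv"))
  if (!is.null(sim$niches)) {
    write_csv_plain(sim$niches, file.path(outd, "niches.csv"))
  }

  say("stage: assemblage")
  assemblage <- stage("assemblage", compute_assemblage(
    sim$ranges, sim$tree, sim$labels,
    n_sites = config$n_sites, n_rand = config$n_rand, seed = config$seed
  ))
  write_csv_plain(tidy(assemblage), file.path(outd, "site_metrics.csv"))
  write_csv_plain(glance(assemblage), file.path(outd, "assemblage_summary.csv"))
  for (nm in names(assemblage$strata)) {
    write_grid_stack(assemblage$strata[[nm]]$grids,
                     file.path(outd, paste0("metrics_", nm, ".grid")))
  }
  cm <- assemblage$strata$total$community
  trip <- which(cm == 1, arr.ind = TRUE)
  write_csv_plain(
    tibble::tibble(site = rownames(cm)[trip[, 1]],
                   species = colnames(cm)[trip[, 2]], presence = 1L),
    file.path(outd, "community_matrix.csv")
  )

  say("stage: environmental space")
  pcspace <- stage("envspace", fit_pca(sim$env, n_components = config$n_components,
                                       bin_width = config$bin_width))
  occupancies <- stage("envspace", project_species(sim$ranges, pcspace))
  density <- stage("envspace", env_density(occupancies, sim$labels))
  zone <- stage("envspace", overlap_zone(occupancies, sim$labels,
                                         required = setdiff(unique(sim$labels$cenocron),
                                                            "Unassigned")))
  mask <- stage("envspace", back_project(zone, pcspace))
  write_csv_plain(tidy(pcspace), file.path(outd, "pca_loadings.csv"))
  write_csv_plain(glance(pcspace), file.path(outd, "pca_variance.csv"))
  write_csv_plain(density, file.path(outd, "env_density.csv"))
  write_csv_plain(tibble::as_tibble(zone), file.path(outd, "transition_zone_bins.csv"))
  write_grid_stack(grid_stack(list(transition_zone = mask * 1), kind = "metric"),
                   file.path(outd, "transition_zone_mask.grid"))

  say("stage: diagnostics")
  diagnostics <- stage("diagnostics", diagnose_regimes(
    assemblage, sim$env, predictions = config$predictions,
    alpha = config$alpha, verdict_metrics = config$verdict_metrics,
    threshold_high = config$threshold_high,
    threshold_low = config$threshold_low
  ))
  write_csv_plain(purrr::map_dfr(diagnostics$anovas, glance),
                  file.path(outd, "anova_results.csv"))
  write_csv_plain(purrr::map_dfr(diagnostics$anovas, tidy),
                  file.path(outd, "tukey_letters.csv"))
  write_csv_plain(diagnostics$correlations, file.path(outd, "correlations.csv"))
  write_csv_plain(tibble::as_tibble(diagnostics$verdicts),
                  file.path(outd, "verdicts.csv"))
  writeLines(c("regime verdict rule:", attr(diagnostics$verdicts, "rule")),
             file.path(outd, "verdict_rule.txt"))

  say("stage: manifest")
  files <- setdiff(list.files(outd), "manifest.json")
  manifest <- list(
    package = "cenozone",
    version = as.character(utils::packageVersion("cenozone")),
    seed = config$seed,
    n_sites = config$n_sites,
    n_rand = config$n_rand,
    bin_width = config$bin_width,
    n_components = config$n_components,
    alpha = config$alpha,
    verdict_thresholds = c(high = config$threshold_high,
                           low = config$threshold_low),
    grid_convention = "row 1 = northernmost row; (row, col) addressing, 1-based",
    checksums = as.list(vapply(stats::setNames(files, files), function(f) {
      as.character(file_checksum(file.path(outd, f)))
    }, character(1)))
  )
  jsonlite::write_json(manifest, file.path(outd, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(
    inputs = sim, assemblage = assemblage, pcspace = pcspace,
    occupancies = occupancies, density = density, zone = zone, mask = mask,
    diagnostics = diagnostics, output_dir = outd
  ))
}

file_checksum <- function(path) {
  unname(tools::md5sum(path))
}

#' Read or write a run configuration as YAML
#'
#' Scenario objects and prediction tables are not serialized; file-based
#' configs reference input paths.
#'
#' @param config a [run_config()] (for writing).
#' @param path YAML file path.
#' @return `write_run_config()` returns `path`; `read_run_config()` a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- config[c("output_dir", "n_sites", "n_rand", "bin_width",
                   "n_components", "alpha", "threshold_high", "threshold_low",
                   "verdict_metrics", "seed")]
  flat$paths <- config$paths
  yaml::write_yaml(flat, path)
  path
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, c(
    list(output_dir = y$output_dir, ranges = y$paths$ranges,
         tree = y$paths$tree, env = y$paths$env, labels = y$paths$labels),
    y[c("n_sites", "n_rand", "bin_width", "n_components", "alpha",
        "threshold_high", "threshold_low", "verdict_metrics", "seed")]
  ))
}
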