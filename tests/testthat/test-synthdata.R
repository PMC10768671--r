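test_that("landscape layers follow their declared gradients", {
  spec <- landscape_spec(10, 8, list(
    landscape_layer("flat", "constant", base = 10),
    landscape_layer("temp", "latitudinal-linear", base = 0, range = 30)
  ), seed = 1)
  env <- generate_landscape(spec)
  expect_true(all(env[["flat"]] == 10))
  rowmeans <- rowMeans(env[["temp"]])
  expect_true(all(diff(rowmeans) > 0))
  expect_equal(rowmeans[1], 0)
  expect_equal(rowmeans[10], 30)
  # every column identical for a purely latitudinal layer
  expect_equal(env[["temp"]][, 1], env[["temp"]][, 5])
})

test_that("conical layers peak at the declared apex (scan over all cells)", {
  spec <- landscape_spec(50, 50, list(
    landscape_layer("elev", "elevational-conical", base = 100, range = 900,
                    apex = c(17, 31))
  ), seed = 7)
  m <- generate_landscape(spec)[["elev"]]
  expect_equal(as.vector(which(m == max(m), arr.ind = TRUE)), c(17, 31))
  expect_equal(m[17, 31], 1000)
})

test_that("landscape generation is deterministic and validates input", {
  spec <- landscape_spec(12, 12, list(
    landscape_layer("n", "noise", base = 0, noise_sd = 2)
  ), seed = 42)
  expect_identical(generate_landscape(spec), generate_landscape(spec))
  spec2 <- landscape_spec(12, 12, list(
    landscape_layer("n", "noise", base = 0, noise_sd = 2)
  ), seed = 43)
  expect_false(identical(generate_landscape(spec)[["n"]],
                         generate_landscape(spec2)[["n"]]))
  expect_error(landscape_spec(1, 10, list(landscape_layer("a", "constant"))),
               ">= 2")
  expect_error(landscape_layer("a", "constant", range = -1), ">= 0")
  expect_error(
    landscape_spec(5, 5, list(landscape_layer("a", "constant"),
                              landscape_layer("a", "noise"))),
    "unique"
  )
})

test_that("simulated phylogenies are ultrametric with monophyletic clades of the requested size and age", {
  clades <- list(
    clade_regime("ca", "conserved", 4, 6, c(x = 0), c(x = 1)),
    clade_regime("cb", "conserved", 5, 9, c(x = 0), c(x = 1)),
    clade_regime("cc", "conserved", 3, 2, c(x = 0), c(x = 1))
  )
  for (seed in 1:50) {
    tr <- simulate_phylogeny(clades, stem_depth = 10, seed = seed)
    expect_equal(length(tr$tip.label), 12)
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    expect_equal(max(ape::node.depth.edgelength(tr)), 10, tolerance = 1e-8)
    for (cl in clades) {
      tips <- grep(paste0("^", cl$clade_name, "_"), tr$tip.label, value = TRUE)
      expect_length(tips, cl$n_tips)
      expect_true(ape::is.monophyletic(tr, tips))
      mrca <- ape::getMRCA(tr, tips)
      crown <- max(ape::node.depth.edgelength(tr)) -
        ape::node.depth.edgelength(tr)[mrca]
      expect_equal(crown, cl$crown_age, tolerance = 1e-8)
    }
  }
})

test_that("a two-tip clade is a cherry with pendant branches at the crown age", {
  tr <- simulate_phylogeny(
    list(clade_regime("solo", "conserved", 2, 5, c(x = 0), c(x = 1))),
    stem_depth = 8, seed = 3
  )
  expect_equal(sort(tr$tip.label), c("solo_1", "solo_2"))
  expect_equal(unname(pendant_lengths(tr)), c(5, 5))
})

test_that("tree simulation is seed-deterministic and validates crown ages", {
  clades <- list(clade_regime("a", "conserved", 3, 4, c(x = 0), c(x = 1)),
                 clade_regime("b", "conserved", 3, 7, c(x = 0), c(x = 1)))
  t1 <- ape::write.tree(simulate_phylogeny(clades, 9, seed = 11))
  t2 <- ape::write.tree(simulate_phylogeny(clades, 9, seed = 11))
  expect_identical(t1, t2)
  expect_error(simulate_phylogeny(clades, 5, seed = 1), "stem_depth")
})

test_that("niche evolution obeys the OU limit, applies stem shifts, and is seeded", {
  strong <- clade_regime("a", "conserved", 4, 3, c(temp = 17), c(temp = 1),
                         ou_strength = 1e6, ou_sigma = 1e-9)
  tr <- simulate_phylogeny(list(strong), 5, seed = 2)
  nt <- evolve_niches(tr, list(strong), 5, seed = 2)
  expect_equal(nt$optimum, rep(17, 4), tolerance = 1e-6)
  expect_equal(nt$sd, rep(1, 4))

  # convergent clade: realized mean optimum approaches ancestral + shift
  conv <- clade_regime("c", "convergent", 6, 3, c(temp = 5), c(temp = 1),
                       ou_strength = 4, ou_sigma = 1, shift = c(temp = 8))
  means <- vapply(1:20, function(s) {
    tr <- simulate_phylogeny(list(conv), 6, seed = s)
    mean(evolve_niches(tr, list(conv), 6, seed = s)$optimum)
  }, numeric(1))
  stationary_sd <- 1 / sqrt(2 * 4)
  expect_lt(abs(mean(means) - (5 + 8)), stationary_sd)

  tr <- simulate_phylogeny(list(conv), 6, seed = 9)
  expect_identical(evolve_niches(tr, list(conv), 6, seed = 9),
                   evolve_niches(tr, list(conv), 6, seed = 9))
  # a tip not assignable to any clade is rejected
  tr_bad <- tr
  tr_bad$tip.label[1] <- "orphan_1"
  expect_error(evolve_niches(tr_bad, list(conv), 6, seed = 1), "orphan")
})

test_that("conserved regime forbids a stem shift", {
  expect_error(
    clade_regime("a", "conserved", 3, 2, c(x = 0), c(x = 1), shift = c(x = 1)),
    "shift"
  )
})

test_that("range realization applies the Gaussian product suitability rule", {
  env <- grid_stack(list(temp = matrix(c(20, 22, 30), 1)), kind = "env")
  nt <- tibble::tibble(species = "s1", clade = "a", variable = "temp",
                       optimum = 22, sd = 2)
  # suitability: exp(-1/2) = 0.6065 at 20; 1 at 22; exp(-8) at 30
  r <- realize_ranges(nt, env, suitability_threshold = 0.6)
  expect_equal(as.vector(r[["s1"]]), c(1, 1, 0))
  r <- realize_ranges(nt, env, suitability_threshold = 0.61)
  expect_equal(as.vector(r[["s1"]]), c(0, 1, 0))
  # optimum exactly equal to a cell's environment: present at any threshold < 1
  r <- realize_ranges(nt, env, suitability_threshold = 0.999)
  expect_equal(as.vector(r[["s1"]]), c(0, 1, 0))
  # optimum 10 sd outside the span: empty range, retained with a warning
  far <- tibble::tibble(species = "s2", clade = "a", variable = "temp",
                        optimum = 30 + 10 * 2, sd = 2)
  expect_warning(r2 <- realize_ranges(far, env, 0.5), "empty")
  expect_equal(sum(r2[["s2"]]), 0)
  expect_true("s2" %in% names(r2))
  # missing environmental variable is named in the error
  bad <- tibble::tibble(species = "s3", clade = "a", variable = "rain",
                        optimum = 0, sd = 1)
  expect_error(realize_ranges(bad, env, 0.5), "rain")
})

test_that("multi-variable suitability multiplies the per-variable kernels", {
  env <- grid_stack(list(a = matrix(1, 1, 1), b = matrix(2, 1, 1)), kind = "env")
  nt <- tibble::tibble(species = "s", clade = "x", variable = c("a", "b"),
                       optimum = c(2, 3), sd = c(1, 1))
  # suitability = exp(-0.5) * exp(-0.5) = exp(-1) = 0.3679
  expect_equal(sum(realize_ranges(nt, env, 0.36)[["s"]]), 1)
  expect_warning(r0 <- realize_ranges(nt, env, 0.37), "empty")
  expect_equal(sum(r0[["s"]]), 0)
})

test_that("the default scenario realizes the regimes it declares", {
  sim <- simulate_scenario(default_scenario())
  expect_equal(length(sim$ranges), 90)
  expect_true(ape::is.ultrametric(sim$tree, tol = 1e-8))
  expect_identical(sort(unique(sim$labels$cenocron)),
                   c("MountainMesoamerican", "Nearctic", "TypicalNeotropical"))

  # conserved clades: richness unimodal along the latitudinal gradient
  # (binned into 5-row blocks to smooth landscape noise)
  for (cl in c("Nearctic", "TypicalNeotropical")) {
    spp <- sim$labels$species[sim$labels$cenocron == cl]
    rich <- stack_richness(grid_stack(sim$ranges$layers[spp], kind = "range"))
    prof <- colSums(matrix(rowSums(rich), nrow = 5))
    peak <- which.max(prof)
    expect_true(all(diff(prof[seq_len(peak)]) >= 0))
    expect_true(all(diff(prof[seq(peak, length(prof))]) <= 0))
  }

  # convergent clade's occupied environmental envelope nests inside the
  # source (Typical Neotropical) clade's envelope
  pcs <- fit_pca(sim$env, n_components = 2, bin_width = 0.1)
  occ <- dplyr::left_join(project_species(sim$ranges, pcs), sim$labels,
                          by = "species")
  key <- paste(occ$bin1, occ$bin2)
  meso <- unique(key[occ$cenocron == "MountainMesoamerican"])
  neo <- unique(key[occ$cenocron == "TypicalNeotropical"])
  expect_true(all(meso %in% neo))
})
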