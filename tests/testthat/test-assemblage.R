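test_that("richness is the sum of the binary layers", {
  a <- matrix(0, 2, 2); a[1, 1] <- 1
  b <- matrix(0, 2, 2); b[2, 2] <- 1
  r <- stack_richness(make_ranges(list(a = a, b = b)))
  expect_equal(sort(as.vector(r)), c(0, 0, 1, 1))
  k <- 5
  mats <- replicate(k, matrix(1, 1, 1), simplify = FALSE)
  names(mats) <- paste0("s", 1:k)
  expect_equal(as.vector(stack_richness(make_ranges(mats))), k)
  expect_error(grid_stack(list(), kind = "range"), "non-empty")
  expect_error(grid_stack(list(a = matrix(0, 2, 2), b = matrix(0, 3, 3))),
               "geometry")
  # total richness equals the summed range sizes
  rr <- random_ranges(8, seed = 5)
  expect_equal(sum(stack_richness(rr)), sum(range_sizes(rr)$range_size))
})

test_that("site sampling is uniform, exhaustive at full draw, and seeded", {
  rr <- random_ranges(2, nr = 5, nc = 5, seed = 1)
  all_sites <- sample_sites(rr, 25, seed = 4)
  expect_equal(nrow(dplyr::distinct(all_sites, row, col)), 25)
  expect_identical(sample_sites(rr, 10, seed = 2), sample_sites(rr, 10, seed = 2))
  expect_error(sample_sites(rr, 26, seed = 1), "exceeds")
  # masked cells are never drawn
  mask <- matrix(TRUE, 5, 5); mask[1, ] <- FALSE
  s <- sample_sites(rr, 20, seed = 3, mask = mask)
  expect_true(all(s$row != 1))
  # inclusion frequencies over repeated seeds match the binomial expectation
  grid <- grid_stack(list(z = matrix(0, 10, 25)), kind = "metric")
  counts <- integer(250)
  for (seed in 1:1000) {
    s <- sample_sites(grid, 5, seed = seed)
    idx <- (s$col - 1L) * 10L + s$row
    counts[idx] <- counts[idx] + 1L
  }
  p <- 5 / 250
  expect_equal(sum(counts), 5000)
  sd_bin <- sqrt(1000 * p * (1 - p))
  # allow the expected far tail over 250 simultaneous binomial checks
  expect_gt(mean(abs(counts - 1000 * p) <= 3 * sd_bin), 0.99)
  expect_true(all(abs(counts - 1000 * p) <= 5 * sd_bin))
})

test_that("community matrices agree with the richness surface and range sizes", {
  rr <- random_ranges(6, nr = 6, nc = 6, seed = 11)
  sites <- sample_sites(rr, 20, seed = 2)
  cm <- build_community_matrix(rr, sites)
  rich <- stack_richness(rr)
  expect_equal(unname(rowSums(cm)), rich[cbind(sites$row, sites$col)])
  expect_true(all(colSums(cm) <= range_sizes(rr)$range_size))
  # single site inside one species' range
  one <- make_ranges(list(only = matrix(c(1, 0, 0, 0), 2, 2)))
  cm1 <- build_community_matrix(one, tibble::tibble(site = 1L, row = 1L, col = 1L))
  expect_equal(as.vector(cm1), 1)
  # all-zero columns are kept
  empty_sp <- make_ranges(list(a = matrix(1, 2, 2), b = matrix(0, 2, 2)))
  cm2 <- build_community_matrix(empty_sp, sample_sites(empty_sp, 4, seed = 1))
  expect_equal(colnames(cm2), c("a", "b"))
  expect_equal(unname(colSums(cm2)), c(4, 0))
})

test_that("per-cell age is the mean pendant branch length of the present species", {
  tr <- toy_tree()  # ((A:1,B:1):1,C:2)
  mk <- function(spp) {
    mats <- lapply(c("A", "B", "C"), function(s) {
      matrix(as.numeric(s %in% spp), 1, 1)
    })
    names(mats) <- c("A", "B", "C")
    make_ranges(mats)
  }
  expect_equal(as.vector(mean_tip_age(mk(c("A", "C")), tr)), 1.5)
  expect_equal(as.vector(mean_tip_age(mk("A"), tr)), 1.0)
  expect_equal(as.vector(mean_tip_age(mk(c("A", "B", "C")), tr)), 4 / 3)
  expect_true(is.na(as.vector(mean_tip_age(mk(character(0)), tr))))
  bad <- make_ranges(list(Z = matrix(1, 1, 1)))
  expect_error(mean_tip_age(bad, tr), "Z")
})

test_that("node depth counts internal nodes to the root, root included", {
  tr <- toy_tree()
  expect_equal(unname(node_depths(tr)[c("A", "B", "C")]), c(2L, 2L, 1L))
  cat5 <- caterpillar_tree(5)
  expect_equal(unname(node_depths(cat5)[paste0("t", 1:5)]), c(4L, 4L, 3L, 2L, 1L))
  expect_equal(mean(node_depths(cat5)), 2.8)
  mats <- list(A = matrix(1, 1, 1), C = matrix(1, 1, 1))
  expect_equal(as.vector(mean_node_depth(make_ranges(mats), tr)), 1.5)
})

test_that("faith_pd matches hand-derived subtree sums including the root path", {
  tr <- toy_tree()
  cm <- rbind(ab = c(A = 1, B = 1, C = 0),
              abc = c(A = 1, B = 1, C = 1),
              c = c(A = 0, B = 0, C = 1),
              none = c(A = 0, B = 0, C = 0))
  pd <- faith_pd(cm, tr)
  # full community spans every edge: 1 + 1 + 1 + 2
  expect_equal(unname(pd[1:3]), c(3, 5, 2))
  expect_true(is.na(pd[4]))
})

test_that("faith_pd equals the brute-force root-path-union oracle on random trees", {
  set.seed(201)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    cm <- matrix(rbinom(8 * n, 1, 0.4), 8, n,
                 dimnames = list(NULL, tr$tip.label))
    got <- faith_pd(cm, tr)
    want <- apply(cm, 1, function(p) brute_pd(tr, colnames(cm)[p == 1]))
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("faith_pd agrees with an independent implementation (picante)", {
  set.seed(17)
  tr <- ape::rtree(9)
  cm <- matrix(rbinom(45, 1, 0.5), 5, 9, dimnames = list(NULL, tr$tip.label))
  cm[1, ] <- 1
  got <- unname(faith_pd(cm, tr))
  ref <- picante::pd(cm, tr, include.root = TRUE)$PD
  keep <- rowSums(cm) > 0
  expect_equal(got[keep], ref[keep], tolerance = 1e-10)
})

test_that("tip-shuffle SES is zero under relabeling symmetry", {
  tr <- toy_tree()
  cm <- rbind(all = c(A = 1, B = 1, C = 1))
  expect_equal(tip_shuffle_ses(cm, tr, n_rand = 25, seed = 1)$ses, 0)
  # star tree: every k-subset has the same PD
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  cm2 <- rbind(s1 = c(a = 1, b = 1, c = 0, d = 0),
               s2 = c(a = 0, b = 0, c = 1, d = 1))
  expect_equal(tip_shuffle_ses(cm2, star, n_rand = 25, seed = 1)$ses, c(0, 0))
})

test_that("derived sister tips score negative SES, matching the exhaustive pair null", {
  tr <- caterpillar_tree(6)
  cm <- rbind(derived = stats::setNames(as.numeric(tr$tip.label %in% c("t1", "t2")),
                                        tr$tip.label))
  res <- tip_shuffle_ses(cm, tr, n_rand = 999, seed = 5)
  # exhaustive null over all unordered tip pairs
  pairs <- utils::combn(tr$tip.label, 2)
  null_pd <- apply(pairs, 2, function(p) brute_pd(tr, p))
  exact_ses <- (brute_pd(tr, c("t1", "t2")) - mean(null_pd)) / stats::sd(null_pd)
  expect_lt(res$ses, 0)
  expect_lt(exact_ses, 0)
  expect_equal(res$ses, exact_ses, tolerance = 0.2)
  expect_identical(tip_shuffle_ses(cm, tr, n_rand = 99, seed = 5),
                   tip_shuffle_ses(cm, tr, n_rand = 99, seed = 5))
})

test_that("weighted endemism redistributes each species' unit mass over its range", {
  a <- matrix(0, 2, 2); a[1, 1] <- 1            # 1 cell -> contributes 1.0
  b <- matrix(1, 2, 2)                          # 4 cells -> 0.25 each
  we <- weighted_endemism(make_ranges(list(a = a, b = b)))
  expect_equal(we[1, 1], 1.25)
  expect_equal(we[2, 2], 0.25)
  expect_equal(sum(we), 2)
  # conservation: grid total = number of non-empty species
  for (seed in 1:10) {
    rr <- random_ranges(12, seed = seed, p_present = 0.15)
    n_nonempty <- sum(range_sizes(rr)$range_size > 0)
    expect_equal(sum(weighted_endemism(rr)), n_nonempty, tolerance = 1e-12)
  }
})

test_that("stratified assemblage computation is consistent with the pooled run", {
  sim <- local({
    sc <- synthetic_scenario(
      landscape_spec(12, 12, list(
        landscape_layer("temp", "latitudinal-linear", base = 0, range = 10,
                        noise_sd = 0.2)
      ), seed = 3),
      list(
        clade_regime("ca", "conserved", 4, 5, c(temp = 3), c(temp = 2),
                     ou_strength = 2, ou_sigma = 0.5),
        clade_regime("cb", "conserved", 4, 5, c(temp = 8), c(temp = 2),
                     ou_strength = 2, ou_sigma = 0.5)
      ), suitability_threshold = 0.3, stem_depth = 8, seed = 21
    )
    simulate_scenario(sc)
  })
  asm <- suppressWarnings(compute_assemblage(
    sim$ranges, sim$tree, sim$labels, n_sites = 50, n_rand = 19, seed = 6
  ))
  expect_setequal(names(asm$strata), c("total", "ca", "cb"))
  # disjoint strata richness sums to total richness
  expect_equal(
    asm$strata$ca$grids[["richness"]] + asm$strata$cb$grids[["richness"]],
    asm$strata$total$grids[["richness"]]
  )
  # community row sums equal richness at the sampled sites
  sm <- asm$strata$total$site_metrics
  expect_equal(unname(rowSums(asm$strata$total$community)), sm$richness)
  # single stratum covering all species reproduces the unstratified metrics
  lab_all <- tibble::tibble(species = names(sim$ranges), cenocron = "only")
  asm_all <- compute_assemblage(sim$ranges, sim$tree, lab_all,
                                n_sites = 50, n_rand = 19, seed = 6)
  expect_equal(asm_all$strata$only$site_metrics,
               asm_all$strata$total$site_metrics)
  # species missing from the labels join the Unassigned stratum
  lab_part <- sim$labels[-1, ]
  asm_part <- suppressWarnings(compute_assemblage(
    sim$ranges, sim$tree, lab_part, n_sites = 30, n_rand = 9, seed = 1
  ))
  expect_true("Unassigned" %in% names(asm_part$strata))
  expect_warning(
    compute_assemblage(sim$ranges, sim$tree, lab_part, n_sites = 30,
                       n_rand = 9, seed = 1),
    "SES skipped"
  )
  # tidy/glance surfaces
  long <- tidy(asm)
  expect_setequal(unique(long$metric),
                  c("richness", "mean_age", "mean_nodes", "weighted_endemism",
                    "pd", "ses_pd"))
  expect_equal(nrow(glance(asm)), 3)
})
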