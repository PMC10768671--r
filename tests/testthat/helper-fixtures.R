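# Shared fixtures and independent oracles. Oracles are deliberately coded
# naively (per-species loops, scalar rules) so they share no code path with
# the package implementations they check.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# caterpillar ((((t1,t2),t3),t4),t5) with unit branches
caterpillar_tree <- function(n = 5) {
  s <- "(t1:1,t2:1)"
  for (k in seq(3, n)) s <- sprintf("(%s:1,t%d:%d)", s, k, k - 1)
  ape::read.tree(text = paste0(s, ";"))
}

make_ranges <- function(mats) grid_stack(mats, kind = "range")

random_ranges <- function(n_species, nr = 6, nc = 6, seed = 1,
                          p_present = 0.3, allow_empty = TRUE) {
  set.seed(seed)
  mats <- lapply(seq_len(n_species), function(i) {
    m <- matrix(rbinom(nr * nc, 1, p_present), nr, nc)
    if (!allow_empty && sum(m) == 0) m[sample(nr * nc, 1)] <- 1
    m
  })
  names(mats) <- paste0("sp", seq_len(n_species))
  make_ranges(mats)
}

# brute-force Faith PD: union of root-path edges over present tips
brute_pd <- function(tree, species) {
  if (length(species) == 0) return(NA_real_)
  root <- length(tree$tip.label) + 1L
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  used <- character(0)
  for (sp in species) {
    tip <- match(sp, tree$tip.label)
    path <- ape::nodepath(tree, from = root, to = tip)
    used <- union(used, paste(path[-length(path)], path[-1]))
  }
  sum(tree$edge.length[match(used, edge_key)])
}

# scalar truth-table classifier, coded straight from the three printed rules
oracle_classify <- function(nn, ns, nm, aff) {
  tot <- nn + ns + nm
  if (tot == 0) return(NA_character_)
  if (nn / tot > 0.8) return("Nearctic")
  if (nn > ns && nn > nm && aff == "northern") return("Nearctic")
  if (nm > ns && nm > nn && aff == "neotropical") return("MountainMesoamerican")
  if (ns / tot > 0.8 && aff == "neotropical") return("TypicalNeotropical")
  "Unassigned"
}

tally_tbl <- function(nn, ns, nm, aff, family = NULL) {
  tibble::tibble(
    family = family %||% paste0("F", seq_along(nn)),
    n_northern = nn, n_southern = ns, n_mesoamerican = nm,
    related_affinity = aff
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bin_key_of <- function(zone) paste(zone$bin1, zone$bin2)

# fake assemblage_result carrying arbitrary site-level series, for
# correlation tests: env value x and metric value y at n sites on a 1-row grid
fake_assemblage <- function(x, y, metric = "richness") {
  n <- length(x)
  sites <- tibble::tibble(site = seq_len(n), row = rep(1L, n), col = seq_len(n))
  sm <- tibble::tibble(site = sites$site, row = sites$row, col = sites$col)
  sm[[metric]] <- y
  asm <- list(
    sites = sites,
    strata = list(g = list(site_metrics = sm)),
    params = list(n_sites = n, n_rand = 0, seed = 0)
  )
  class(asm) <- "assemblage_result"
  env <- grid_stack(list(v = matrix(x, nrow = 1)), kind = "env")
  list(assemblage = asm, env = env)
}
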