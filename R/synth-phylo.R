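#' Describe a clade and its niche-evolution regime
#'
#' Each clade plays the role of one cenocron in a synthetic scenario. Under
#' the `conserved` regime tips evolve toward the clade's ancestral optimum;
#' under the `convergent` regime a one-off displacement (`shift`) is applied
#' at the clade stem, so the clade radiates toward a novel optimum
#' (`optimum + shift`) away from its ancestral value.
#'
#' @param clade_name clade label; tips are named `<clade_name>_<i>`.
#' @param regime `"conserved"` or `"convergent"`.
#' @param n_tips number of tips (>= 2).
#' @param crown_age crown age in Ma (> 0).
#' @param optimum named numeric vector: ancestral niche optimum per
#'   environmental variable.
#' @param niche_sd named numeric vector (> 0): per-variable tolerance
#'   (Gaussian suitability sd), shared by all tips of the clade.
#' @param ou_strength Ornstein-Uhlenbeck pull rate alpha (>= 0; 0 = Brownian).
#' @param ou_sigma OU diffusion rate (per-variable, recycled).
#' @param shift named numeric vector: optimum displacement applied once at
#'   the clade stem. Must be all zero under the conserved regime.
#' @return a `clade_regime` list.
#' @export
clade_regime <- function(clade_name, regime = c("conserved", "convergent"),
                         n_tips, crown_age, optimum, niche_sd,
                         ou_strength = 1, ou_sigma = 1, shift = NULL) {
  regime <- match.arg(regime)
  stopifnot(is.character(clade_name), length(clade_name) == 1L, nzchar(clade_name))
  if (n_tips < 2) stop("`n_tips` must be >= 2", call. = FALSE)
  if (crown_age <= 0) stop("`crown_age` must be > 0", call. = FALSE)
  if (is.null(names(optimum)) || anyNA(names(optimum))) {
    stop("`optimum` must be a named vector (names = environmental variables)",
         call. = FALSE)
  }
  vars <- names(optimum)
  niche_sd <- rep_len(niche_sd, length(vars))
  names(niche_sd) <- vars
  if (any(niche_sd <= 0)) stop("`niche_sd` must be > 0", call. = FALSE)
  if (ou_strength < 0) stop("`ou_strength` must be >= 0", call. = FALSE)
  if (is.null(shift)) shift <- stats::setNames(numeric(length(vars)), vars)
  shift <- shift[vars]
  shift[is.na(shift)] <- 0
  names(shift) <- vars
  if (regime == "conserved" && any(shift != 0)) {
    stop("conserved regime implies zero `shift`", call. = FALSE)
  }
  structure(
    list(clade_name = clade_name, regime = regime, n_tips = as.integer(n_tips),
         crown_age = crown_age, optimum = optimum, niche_sd = niche_sd,
         ou_strength = ou_strength,
         ou_sigma = stats::setNames(rep_len(ou_sigma, length(vars)), vars),
         shift = shift),
    class = "clade_regime"
  )
}

check_clades <- function(clades) {
  ok <- vapply(clades, inherits, logical(1), what = "clade_regime")
  if (length(clades) == 0L || !all(ok)) {
    stop("`clades` must be a non-empty list of clade_regime objects", call. = FALSE)
  }
  nms <- vapply(clades, `[[`, character(1), "clade_name")
  if (anyDuplicated(nms)) stop("clade names must be unique", call. = FALSE)
  stats::setNames(clades, nms)
}

# Pure-birth crown tree rescaled to an exact crown age.
yule_clade <- function(n_tips, crown_age, clade_name) {
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (crown_age / depth)
  tr$tip.label <- paste0(clade_name, "_", seq_len(n_tips))
  tr
}

#' Simulate a clade-structured ultrametric phylogeny
#'
#' Each clade gets a pure-birth (Yule) crown topology rescaled to its crown
#' age, then all clade stems are attached at the root at depth `stem_depth`,
#' so the tree is ultrametric and every clade monophyletic. With more than
#' two clades the root is a soft polytomy of clade stems.
#'
#' @param clades list of [clade_regime()] objects.
#' @param stem_depth root depth in Ma; must be >= every crown age.
#' @param seed integer seed.
#' @return an [ape::phylo] tree with branch lengths in Ma.
#' @export
simulate_phylogeny <- function(clades, stem_depth, seed = 1L) {
  clades <- check_clades(clades)
  ages <- vapply(clades, `[[`, numeric(1), "crown_age")
  if (any(ages > stem_depth)) {
    stop("crown_age exceeds stem_depth for clade(s): ",
         paste(names(clades)[ages > stem_depth], collapse = ", "), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  subtrees <- lapply(clades, function(cl) yule_clade(cl$n_tips, cl$crown_age, cl$clade_name))
  if (length(subtrees) == 1L) {
    tr <- subtrees[[1]]
    tr$root.edge <- stem_depth - clades[[1]]$crown_age
    return(tr)
  }
  parts <- vapply(seq_along(subtrees), function(i) {
    nwk <- ape::write.tree(subtrees[[i]])
    stem <- stem_depth - clades[[i]]$crown_age
    paste0(sub(";$", "", nwk), ":", format(stem, digits = 17))
  }, character(1))
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

# Exact OU transition along one branch: child ~ Normal(
#   theta + (parent - theta) * exp(-alpha t), sigma^2 (1 - exp(-2 alpha t)) / (2 alpha))
# alpha = 0 degenerates to Brownian motion (variance sigma^2 t).
ou_step <- function(parent, theta, alpha, sigma, t) {
  if (alpha > 0) {
    w <- exp(-alpha * t)
    mu <- theta + (parent - theta) * w
    v <- sigma^2 * (1 - exp(-2 * alpha * t)) / (2 * alpha)
  } else {
    mu <- parent
    v <- sigma^2 * t
  }
  stats::rnorm(length(parent), mu, sqrt(pmax(v, 0)))
}

# Preorder OU simulation of one variable over one clade's subtree
# (stem included): returns named tip values.
ou_on_clade <- function(tree, tips, root_value, theta, alpha, sigma, stem_length) {
  sub <- ape::keep.tip(tree, tips)
  n <- length(sub$tip.label)
  nnode <- sub$Nnode
  vals <- numeric(n + nnode)
  root <- n + 1L
  vals[root] <- ou_step(root_value, theta, alpha, sigma, stem_length)
  sub <- stats::reorder(sub, "cladewise")  # parent edges precede child edges
  edges <- sub$edge
  lens <- sub$edge.length
  for (i in seq_len(nrow(edges))) {
    par <- edges[i, 1]; chi <- edges[i, 2]
    vals[chi] <- ou_step(vals[par], theta, alpha, sigma, lens[i])
  }
  stats::setNames(vals[seq_len(n)], sub$tip.label)
}

#' Evolve niche optima on a simulated phylogeny
#'
#' Traits evolve along branches as an Ornstein-Uhlenbeck walk toward the
#' clade's effective optimum (`optimum + shift`), starting from the ancestral
#' `optimum` at the base of the clade stem. Convergent clades therefore
#' realize optima clustered away from the ancestral value. Tolerances
#' (`niche_sd`) are inherited unchanged from the clade.
#'
#' @param tree tree from [simulate_phylogeny()]; every tip must belong to
#'   exactly one clade (by the `<clade_name>_<i>` convention).
#' @param clades list of [clade_regime()] objects.
#' @param stem_depth root depth used when simulating the tree (gives stem
#'   branch lengths).
#' @param seed integer seed.
#' @return a tibble with columns `species`, `clade`, `variable`, `optimum`,
#'   `sd` (one row per species x variable).
#' @export
evolve_niches <- function(tree, clades, stem_depth, seed = 1L) {
  clades <- check_clades(clades)
  assign_clade <- function(tip) {
    hits <- names(clades)[vapply(names(clades), function(nm) {
      startsWith(tip, paste0(nm, "_"))
    }, logical(1))]
    if (length(hits) != 1L) {
      stop("tip without (unique) clade assignment: ", tip, call. = FALSE)
    }
    hits
  }
  tip_clade <- vapply(tree$tip.label, assign_clade, character(1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rows <- purrr::map_dfr(names(clades), function(nm) {
    cl <- clades[[nm]]
    tips <- tree$tip.label[tip_clade == nm]
    stem <- stem_depth - cl$crown_age
    purrr::map_dfr(names(cl$optimum), function(v) {
      vals <- ou_on_clade(
        tree, tips,
        root_value = cl$optimum[[v]],
        theta = cl$optimum[[v]] + cl$shift[[v]],
        alpha = cl$ou_strength,
        sigma = cl$ou_sigma[[v]],
        stem_length = stem
      )
      tibble::tibble(
        species = names(vals), clade = nm, variable = v,
        optimum = unname(vals), sd = cl$niche_sd[[v]]
      )
    })
  })
  dplyr::arrange(rows, .data$clade, .data$species, .data$variable)
}
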