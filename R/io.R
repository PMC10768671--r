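#' Write a grid stack as a plain-text multi-layer grid file
#'
#' Format: for each layer a header line `#layer <name> <n_rows> <n_cols>`
#' followed by `n_rows` tab-separated lines of cell values (`NA` = nodata),
#' row 1 (north) first. Values round-trip exactly (written with full
#' precision).
#'
#' @param x a `grid_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid_stack <- function(x, path) {
  stopifnot(inherits(x, "grid_stack"))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("#grid_stack kind=%s layers=%d", x$kind, length(x)), con)
  for (nm in names(x)) {
    m <- x[[nm]]
    writeLines(sprintf("#layer %s %d %d", nm, nrow(m), ncol(m)), con)
    writeLines(apply(m, 1, function(r) {
      paste(format(r, digits = 17, trim = TRUE, scientific = TRUE), collapse = "\t")
    }), con)
  }
  invisible(path)
}

#' Read a plain-text multi-layer grid file
#'
#' @param path file written by [write_grid_stack()].
#' @param kind grid kind to stamp on the result (default: as recorded in the
#'   file header).
#' @return a `grid_stack`.
#' @export
read_grid_stack <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#grid_stack")) {
    stop("not a grid_stack file: ", path, call. = FALSE)
  }
  file_kind <- sub('^#grid_stack kind=([a-z]+).*$', "\\1", lines[1])
  headers <- which(startsWith(lines, "#layer "))
  if (length(headers) == 0) stop("no layers in ", path, call. = FALSE)
  layers <- list()
  for (h in headers) {
    parts <- strsplit(lines[h], " ", fixed = TRUE)[[1]]
    nm <- parts[2]
    nr <- as.integer(parts[3]); nc <- as.integer(parts[4])
    block <- lines[(h + 1):(h + nr)]
    vals <- lapply(strsplit(block, "\t", fixed = TRUE), function(v) {
      out <- rep(NA_real_, length(v))
      ok <- v != "NA"
      out[ok] <- as.numeric(v[ok])
      out
    })
    if (any(lengths(vals) != nc)) {
      stop("malformed layer '", nm, "' in ", path, call. = FALSE)
    }
    layers[[nm]] <- matrix(unlist(vals), nrow = nr, ncol = nc, byrow = TRUE)
  }
  grid_stack(layers, kind = kind %||% file_kind)
}

#' Read a set of binary species ranges
#'
#' Layer names are species names; values must be 0/1 (NA treated as 0).
#'
#' @param path a grid-stack file.
#' @return a `grid_stack` of kind `"range"`.
#' @export
read_ranges <- function(path) {
  g <- read_grid_stack(path, kind = "range")
  g$layers <- lapply(g$layers, function(m) {
    m[is.na(m)] <- 0
    if (!all(m %in% c(0, 1))) stop("ranges must be binary 0/1", call. = FALSE)
    m
  })
  g
}

#' Read an environmental layer stack
#'
#' @param path a grid-stack file.
#' @return a `grid_stack` of kind `"env"`.
#' @export
read_env <- function(path) read_grid_stack(path, kind = "env")

#' Read a dated phylogeny (Newick)
#'
#' @param path Newick file; must parse to a single rooted tree with branch
#'   lengths.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("unparseable Newick file: ", path, call. = FALSE)
  }
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths: ", path, call. = FALSE)
  }
  tr
}

#' Read a species label table (CSV with columns species, cenocron)
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_labels <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("species", "cenocron")
  if (!all(need %in% names(df))) {
    stop("label CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

normalize_names <- function(x) gsub(" ", "_", trimws(x), fixed = TRUE)

#' Reconcile tree tips with range species names
#'
#' Normalizes spaces to underscores on both sides, then reports tips absent
#' from the ranges and species absent from the tree. The run can proceed as
#' long as every range species maps onto a tip.
#'
#' @param tree an [ape::phylo] tree.
#' @param ranges a range `grid_stack`.
#' @return list `tree`, `ranges` (names normalized), `tips_without_range`,
#'   `species_without_tip`.
#' @export
reconcile_names <- function(tree, ranges) {
  tree$tip.label <- normalize_names(tree$tip.label)
  names(ranges$layers) <- normalize_names(names(ranges$layers))
  list(
    tree = tree, ranges = ranges,
    tips_without_range = setdiff(tree$tip.label, names(ranges)),
    species_without_tip = setdiff(names(ranges), tree$tip.label)
  )
}
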