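#' Describe one synthetic environmental layer
#'
#' Layers come in four kinds. `latitudinal-linear` increases linearly from the
#' northern edge (row 1, value `base`) to the southern edge (value
#' `base + range`), emulating a temperature gradient. `elevational-conical`
#' peaks at an apex cell (value `base + range`) and decays linearly with
#' chebyshev distance to `base`, emulating a mountain-driven variable such as
#' elevation or orographic moisture. `noise` is pure Gaussian noise around
#' `base`, and `constant` is flat. Independent Gaussian noise of sd `noise_sd`
#' is added on top of every kind.
#'
#' @param name layer name (unique within a landscape).
#' @param kind one of `"latitudinal-linear"`, `"elevational-conical"`,
#'   `"noise"`, `"constant"`.
#' @param base baseline value of the layer.
#' @param range total amplitude of the deterministic gradient (>= 0).
#' @param noise_sd standard deviation of additive cell noise (>= 0).
#' @param apex `(row, col)` of the cone apex; defaults to the grid centre.
#'   Ignored for non-conical kinds.
#' @return a `landscape_layer` list.
#' @export
landscape_layer <- function(name,
                            kind = c("latitudinal-linear", "elevational-conical",
                                     "noise", "constant"),
                            base = 0, range = 0, noise_sd = 0, apex = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (range < 0) stop("`range` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(name = name, kind = kind, base = base, range = range,
         noise_sd = noise_sd, apex = apex),
    class = "landscape_layer"
  )
}

#' Specify a synthetic landscape
#'
#' @param n_rows,n_cols grid dimensions (both >= 2). Row 1 is the
#'   northernmost row.
#' @param layers list of [landscape_layer()] descriptions with unique names.
#' @param seed integer seed controlling the noise fields.
#' @return a `landscape_spec` list.
#' @export
landscape_spec <- function(n_rows, n_cols, layers, seed = 1L) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 2 || n_cols < 2) {
    stop("`n_rows` and `n_cols` must both be >= 2", call. = FALSE)
  }
  if (!is.list(layers) || length(layers) == 0L) {
    stop("`layers` must be a non-empty list of landscape_layer objects", call. = FALSE)
  }
  ok <- vapply(layers, inherits, logical(1), what = "landscape_layer")
  if (!all(ok)) stop("every element of `layers` must be a landscape_layer", call. = FALSE)
  nms <- vapply(layers, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("layer names must be unique; duplicated: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         layers = stats::setNames(layers, nms), seed = as.integer(seed)),
    class = "landscape_spec"
  )
}

layer_gradient <- function(layer, n_rows, n_cols) {
  switch(layer$kind,
    "latitudinal-linear" = {
      rowvals <- layer$base + layer$range * (seq_len(n_rows) - 1) / (n_rows - 1)
      matrix(rowvals, n_rows, n_cols)
    },
    "elevational-conical" = {
      apex <- layer$apex %||% c(ceiling(n_rows / 2), ceiling(n_cols / 2))
      if (apex[1] < 1 || apex[1] > n_rows || apex[2] < 1 || apex[2] > n_cols) {
        stop("cone apex lies outside the grid", call. = FALSE)
      }
      d <- outer(abs(seq_len(n_rows) - apex[1]), abs(seq_len(n_cols) - apex[2]), pmax)
      dmax <- max(d)
      layer$base + layer$range * (1 - d / dmax)
    },
    "noise" = matrix(layer$base, n_rows, n_cols),
    "constant" = matrix(layer$base, n_rows, n_cols)
  )
}

#' Generate the environmental grid stack of a landscape
#'
#' Deterministic given the spec (the spec's `seed` drives all noise).
#'
#' @param spec a [landscape_spec()].
#' @return a `grid_stack` of kind `"env"` with one layer per description.
#' @export
#' @examples
#' spec <- landscape_spec(10, 10, list(
#'   landscape_layer("temperature", "latitudinal-linear", base = 10, range = 20),
#'   landscape_layer("moisture", "elevational-conical", base = 200, range = 800)
#' ))
#' env <- generate_landscape(spec)
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  layers <- lapply(spec$layers, function(ly) {
    m <- layer_gradient(ly, spec$n_rows, spec$n_cols)
    if (ly$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, ly$noise_sd), nrow(m), ncol(m))
    }
    m
  })
  grid_stack(layers, kind = "env")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Save/restore the RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
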