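#' Lightweight multi-layer grid container
#'
#' A `grid_stack` holds one or more co-registered layers (numeric matrices of
#' identical dimension) on a shared raster geometry. Row 1 is the northernmost
#' row; cells are addressed `(row, col)`. It is the common currency for
#' environmental layers, binary species ranges and per-cell metric surfaces.
#'
#' @param layers named list of numeric matrices, all with identical `dim()`.
#' @param kind one of `"env"`, `"range"`, `"metric"`; purely informational.
#' @return an object of class `grid_stack`.
#' @export
grid_stack <- function(layers, kind = c("env", "range", "metric")) {
  kind <- match.arg(kind)
  if (!is.list(layers) || length(layers) == 0L) {
    stop("`layers` must be a non-empty named list of matrices", call. = FALSE)
  }
  nm <- names(layers)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("every layer must have a unique non-empty name", call. = FALSE)
  }
  dims <- lapply(layers, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop("every layer must be a matrix", call. = FALSE)
  }
  ref <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, ref), logical(1)))) {
    stop("all layers must share one geometry (identical dimensions)", call. = FALSE)
  }
  layers <- lapply(layers, function(m) {
    storage.mode(m) <- "double"  # canonical storage so text round trips exactly
    m
  })
  structure(
    list(layers = layers, n_rows = ref[1], n_cols = ref[2], kind = kind),
    class = "grid_stack"
  )
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf(
    "<grid_stack [%s]> %d layer(s) on a %d x %d grid\n",
    x$kind, length(x$layers), x$n_rows, x$n_cols
  ))
  cat("layers:", paste(utils::head(names(x$layers), 8), collapse = ", "),
      if (length(x$layers) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
names.grid_stack <- function(x) names(x$layers)

#' @export
dim.grid_stack <- function(x) c(x$n_rows, x$n_cols)

#' @export
length.grid_stack <- function(x) length(x$layers)

#' @export
`[[.grid_stack` <- function(x, i) x$layers[[i]]

same_geometry <- function(a, b) {
  identical(dim(a), dim(b))
}

stopifnot_shared_geometry <- function(x, y, what = "inputs") {
  if (!same_geometry(x, y)) {
    stop(sprintf(
      "%s are on different geometries: %dx%d vs %dx%d",
      what, dim(x)[1], dim(x)[2], dim(y)[1], dim(y)[2]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert a grid stack to a long tibble
#'
#' @param x a `grid_stack`.
#' @param ... unused.
#' @return a tibble with columns `row`, `col`, `layer`, `value`; `NA` cells
#'   (nodata) are kept so the frame always has `n_rows * n_cols` rows per layer.
#' @export
as_tibble.grid_stack <- function(x, ...) {
  purrr::imap_dfr(x$layers, function(m, nm) {
    tibble::tibble(
      row = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      layer = nm,
      value = as.vector(m)
    )
  })
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Map of the layers in a grid stack
#'
#' Draws each layer as a raster panel with row 1 at the top (north).
#'
#' @param object a `grid_stack`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.grid_stack <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row (1 = north)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
NULL
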