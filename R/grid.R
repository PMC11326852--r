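#' Choose map grid dimensions for a cell and resolution
#'
#' Computes the real-space sampling grid for maps of a cell at a given
#' resolution limit. The nominal spacing is `d_min / oversampling` on every
#' axis; each dimension is the smallest even integer of voxels covering the
#' cell edge at that spacing, optionally rounded up further to a multiple of
#' a patch dimension for the transformer tokenizer. Voxel `i` on an axis of
#' `N` voxels samples fractional coordinate `i/N` (origin at index 0), so
#' the realized spacing is `edge/N <= d_min/oversampling`.
#'
#' @param cell A [unit_cell].
#' @param d_min Resolution limit in Angstrom (> 0).
#' @param oversampling Grid oversampling factor (>= 2).
#' @param multiple_of Optional integer vector (length 1 or 3): round each
#'   dimension up to a multiple of this (patch divisibility).
#' @return A list with `dims` (integer length 3) and `spacing` (nominal
#'   Angstrom per voxel, length 3).
#' @examples
#' build_grid(unit_cell(41, 30, 24), d_min = 1.5, oversampling = 3)
#' @export
build_grid <- function(cell, d_min, oversampling, multiple_of = NULL) {
  stopifnot(inherits(cell, "unit_cell"))
  if (!is.numeric(d_min) || d_min <= 0) {
    stop("invalid resolution: d_min must be > 0", call. = FALSE)
  }
  if (!is.numeric(oversampling) || oversampling < 2) {
    stop("oversampling must be >= 2", call. = FALSE)
  }
  spacing <- d_min / oversampling
  dims <- vapply(cell_edges(cell), function(edge) {
    n <- ceiling(edge / spacing - 1e-9)
    if (n %% 2L == 1L) n <- n + 1L
    as.integer(n)
  }, integer(1L))
  if (!is.null(multiple_of)) {
    m <- as.integer(rep_len(multiple_of, 3L))
    stopifnot(all(m >= 1L))
    dims <- as.integer(ceiling(dims / m) * m)
    dims <- dims + as.integer(dims %% 2L) # keep dims even
  }
  list(dims = dims, spacing = rep(spacing, 3L))
}

#' Real-valued 3D map on a cell grid
#'
#' @param values Numeric 3D array (N1 x N2 x N3).
#' @param cell A [unit_cell].
#' @param kind One of "density", "patterson", "prediction", "partial".
#' @param spacing Nominal Angstrom per voxel (length 1 or 3); defaults to
#'   `cell edge / dims`.
#' @param normalized Logical: values already scaled to `[-1, 1]` with
#'   max |value| = 1 (or all zero).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, cell,
                        kind = c("density", "patterson", "prediction",
                                 "partial"),
                        spacing = NULL, normalized = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.array(values), length(dim(values)) == 3L,
            inherits(cell, "unit_cell"))
  dims <- dim(values)
  if (is.null(spacing)) spacing <- cell_edges(cell) / dims
  spacing <- rep_len(spacing, 3L)
  structure(list(values = values, dims = as.integer(dims), cell = cell,
                 kind = kind, spacing = spacing, normalized = normalized),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("%s map: %d x %d x %d voxels, cell %.2f x %.2f x %.2f A%s\n",
              x$kind, x$dims[1L], x$dims[2L], x$dims[3L],
              x$cell$a, x$cell$b, x$cell$c,
              if (x$normalized) ", normalized" else ""))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Scale a map to the range [-1, 1]
#'
#' Divides all voxel values by the maximum absolute value, preserving the
#' zero level and the sign pattern (the density zero level is physically
#' meaningful, and the model's tanh output head is sign-symmetric, so
#' max-abs scaling rather than min-max is used). All-zero maps are returned
#' unchanged apart from the `normalized` flag. Idempotent.
#'
#' @param m A [volume_grid].
#' @return The normalized [volume_grid].
#' @export
normalize_map <- function(m) {
  stopifnot(inherits(m, "volume_grid"))
  if (any(!is.finite(m$values))) {
    stop("invalid map: non-finite voxel values", call. = FALSE)
  }
  peak <- max(abs(m$values))
  if (peak > 0) m$values <- m$values / peak
  m$normalized <- TRUE
  m
}
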