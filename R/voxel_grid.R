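#' 3-D voxel grid with physical spacing
#'
#' A `voxel_grid` is the carrier for every scalar field in the pipeline: the
#' raw image, the energy field, the size field, and binary masks. It couples a
#' 3-D numeric array in `(z, y, x)` axis order with the per-axis physical
#' voxel length in micrometres. Array indices are 1-based inside R; physical
#' positions are `(index - 1) * spacing + origin` so that voxel `(1,1,1)` sits
#' at `origin`.
#'
#' @param values 3-D numeric (or logical) array, axes ordered `(z, y, x)`.
#' @param spacing numeric length-3, voxel edge length per axis in micrometres
#'   (um); all entries must be positive. A scalar is recycled to all axes.
#' @param origin numeric length-3, physical coordinate (um) of voxel
#'   `(1,1,1)`. Default zeros.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 8, 8)), spacing = c(2, 1, 1))
#' dim(g)
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array ordered (z, y, x)", call. = FALSE)
  if (is.logical(values)) storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("`values` must be finite everywhere", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel lengths (um)", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (z,y,x), spacing %s um\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  rng <- range(x$values)
  cat(sprintf("  values in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Physical coordinates of voxel indices
#'
#' @param grid a [voxel_grid()].
#' @param index integer matrix (n x 3) of 1-based `(z, y, x)` voxel indices,
#'   or a length-3 vector.
#' @return numeric matrix (n x 3) of positions in um.
#' @export
voxel_to_um <- function(grid, index) {
  if (is.null(dim(index))) index <- matrix(index, ncol = 3L)
  sweep(sweep(index - 1, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
}

#' Voxel indices nearest to physical coordinates
#'
#' @param grid a [voxel_grid()].
#' @param pos numeric matrix (n x 3) of `(z, y, x)` positions in um.
#' @return integer matrix (n x 3) of 1-based voxel indices, clamped to the
#'   grid bounds.
#' @export
um_to_voxel <- function(grid, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3L)
  idx <- round(sweep(sweep(pos, 2L, grid$origin, "-"), 2L, grid$spacing, "/")) + 1
  d <- dim(grid$values)
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1), d[a])
  storage.mode(idx) <- "integer"
  idx
}

# physical extent (um) of the grid along each axis
grid_extent <- function(grid) dim(grid$values) * grid$spacing

stopifnot_voxel_grid <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "voxel_grid"))
    stop(sprintf("`%s` must be a voxel_grid", arg), call. = FALSE)
  invisible(x)
}
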