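#' Colored z-projections of a vector network
#'
#' Renders strand centerline points into a 2-D axial (z) projection with
#' colors encoding strand identity (seeded random color per strand), depth
#' (viridis colormap over z), or local direction (axis components mapped to
#' RGB). Where strands overlap in projection, the shallowest (smallest z)
#' point wins.
#'
#' @param network a `vessel_network`.
#' @param grid the [voxel_grid()] defining the raster and extent.
#' @param mode `"strand"`, `"depth"` or `"direction"`.
#' @param seed seed for the per-strand color assignment.
#' @param path optional PNG output path.
#' @return `y x x x 3` RGB array in `[0, 1]`, invisibly.
#' @export
render_projections <- function(network, grid,
                               mode = c("strand", "depth", "direction"),
                               seed = 1L, path = NULL) {
  mode <- match.arg(mode)
  if (!length(network$strands)) stop("empty network", call. = FALSE)
  d <- dim(grid$values)
  img <- array(0, c(d[2], d[3], 3))
  zbuf <- matrix(Inf, d[2], d[3])
  set.seed(seed)
  hues <- stats::runif(length(network$strands))
  depth_cols <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255
  zmax <- grid_extent(grid)[1]
  for (si in seq_along(network$strands)) {
    st <- network$strands[[si]]
    pts <- sweep(st$points, 2L, grid$origin, "-")
    idx <- round(sweep(pts, 2L, grid$spacing, "/")) + 1
    n <- nrow(pts)
    dirs <- NULL
    if (mode == "direction") {
      ## spatial difference quotient along the trajectory
      nb <- rbind(pts[2, , drop = FALSE], pts[-1, , drop = FALSE])
      pv <- rbind(pts[1, , drop = FALSE], pts[-n, , drop = FALSE])
      dirs <- nb - pv
      nrm <- sqrt(rowSums(dirs^2)); nrm[nrm == 0] <- 1
      dirs <- abs(dirs / nrm)
    }
    for (i in seq_len(n)) {
      y <- idx[i, 2]; x <- idx[i, 3]
      if (y < 1 || y > d[2] || x < 1 || x > d[3]) next
      if (pts[i, 1] >= zbuf[y, x]) next
      zbuf[y, x] <- pts[i, 1]
      img[y, x, ] <- switch(mode,
        strand = grDevices::col2rgb(grDevices::hsv(hues[si], 0.85, 1)) / 255,
        depth = depth_cols[, pmin(256L, pmax(1L,
          1L + floor(255 * pts[i, 1] / max(zmax, 1e-9))))],
        direction = dirs[i, ])
    }
  }
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}
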