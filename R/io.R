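#' Read a multi-page TIFF stack as a voxel grid
#'
#' Pages are z slices (ImageJ convention: z pages, y rows, x columns).
#' Unsigned 8/16-bit and 32-bit float stacks are supported; 16-bit signed
#' data are accepted and offset to non-negative (the offset is reported in
#' a message and stored as attribute `intensity_offset`). Voxel spacing is
#' not read from TIFF tags; pass it explicitly. A float stack written by
#' [write_stack()] is un-rescaled through its sidecar metadata file.
#'
#' @param path TIFF file path.
#' @param spacing per-axis voxel lengths (um).
#' @return A [voxel_grid()].
#' @export
read_stack <- function(path, spacing = c(1, 1, 1)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  pages <- if (!is.null(meta) && identical(meta$dtype, "float32"))
    tiff::readTIFF(path, all = TRUE) # float samples: read as stored
  else tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("expected a 3-D stack: TIFF has a single page", call. = FALSE)
  if (length(dim(pages[[1]])) != 2L)
    stop("unsupported TIFF layout (expected one grayscale sample per pixel)",
         call. = FALSE)
  d <- c(length(pages), dim(pages[[1]]))
  values <- array(0, d)
  for (z in seq_len(d[1])) values[z, , ] <- pages[[z]]
  ## 16-bit signed data arrive reinterpreted as unsigned; fold back
  if (identical(attr(pages[[1]], "sample.format"), "int")) {
    bits <- attr(pages[[1]], "bits.per.sample")
    if (!is.null(bits) && bits == 16L)
      values[values > 32767] <- values[values > 32767] - 65536
  }
  if (!is.null(meta) && identical(meta$dtype, "float32"))
    values <- values * meta$scale + meta$offset
  offset <- 0
  if (min(values) < 0 && is.null(meta)) {
    offset <- -min(values)
    values <- values + offset
    message(sprintf("signed input offset to non-negative by +%g", offset))
  }
  out <- voxel_grid(values, spacing)
  attr(out, "intensity_offset") <- offset
  out
}

#' Write a voxel grid as a multi-page TIFF stack
#'
#' `uint8`/`uint16` stacks round-trip bit-identically (values must be
#' integers within range). `float32` stacks are stored at single precision
#' after an affine rescale to the unit interval; the rescale is recorded in
#' a sidecar `<path>.json` so [read_stack()] restores the original values
#' (to float precision).
#'
#' @param grid a [voxel_grid()].
#' @param path output TIFF path.
#' @param dtype one of `"float32"`, `"uint16"`, `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path, dtype = c("float32", "uint16",
                                              "uint8")) {
  stopifnot_voxel_grid(grid)
  dtype <- match.arg(dtype)
  v <- grid$values
  d <- dim(v)
  if (dtype == "float32") {
    lo <- min(v); hi <- max(v)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(d[1]), function(z) (v[z, , ] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(dtype = "float32", offset = lo,
                              scale = scale, dim = d,
                              spacing_um = grid$spacing),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    maxval <- if (dtype == "uint16") 65535 else 255
    if (any(v < 0) || any(v > maxval) || any(v != round(v)))
      stop(sprintf("values must be integers in [0, %d] for %s",
                   maxval, dtype), call. = FALSE)
    pages <- lapply(seq_len(d[1]), function(z) v[z, , ] / maxval)
    tiff::writeTIFF(pages, path,
                    bits.per.sample = if (dtype == "uint16") 16L else 8L,
                    reduce = FALSE)
  }
  invisible(path)
}

#' Export vertices, edges and strands as CSV tables
#'
#' Voxel indices are exported 0-based in `(z, y, x)` order; physical
#' positions are micrometres.
#'
#' @param vertices vertex data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vertices_csv <- function(vertices, path) {
  out <- data.frame(id = vertices$id, z = vertices$z - 1L,
                    y = vertices$y - 1L, x = vertices$x - 1L,
                    z_um = vertices$z_um, y_um = vertices$y_um,
                    x_um = vertices$x_um,
                    radius_um = vertices$radius_um,
                    energy = vertices$energy)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vertices_csv
#' @param edges edge list from [extract_edges()].
#' @param trace_path optional path for the long-format per-point trace
#'   table.
#' @export
write_edges_csv <- function(edges, path, trace_path = NULL) {
  summ <- data.frame(
    id = seq_along(edges),
    vertex_a = vapply(edges, `[[`, numeric(1), "vertex_a"),
    vertex_b = vapply(edges, `[[`, numeric(1), "vertex_b"),
    max_energy = vapply(edges, `[[`, numeric(1), "max_energy"),
    n_points = vapply(edges, function(e) nrow(e$trace), integer(1)))
  utils::write.csv(summ, path, row.names = FALSE)
  if (!is.null(trace_path)) {
    tr <- do.call(rbind, lapply(seq_along(edges), function(i) {
      e <- edges[[i]]
      data.frame(edge = i, point = seq_len(nrow(e$trace)),
                 z = e$trace[, 1] - 1L, y = e$trace[, 2] - 1L,
                 x = e$trace[, 3] - 1L, radius_um = e$radii_um,
                 energy = e$energies)
    }))
    if (is.null(tr)) tr <- data.frame(edge = integer(), point = integer(),
                                      z = integer(), y = integer(),
                                      x = integer(), radius_um = numeric(),
                                      energy = numeric())
    utils::write.csv(tr, trace_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_vertices_csv
#' @param network a `vessel_network`.
#' @param summary_path optional path for the bifurcation/endpoint summary
#'   CSV.
#' @export
write_strands_csv <- function(network, path, summary_path = NULL) {
  tr <- do.call(rbind, lapply(seq_along(network$strands), function(i) {
    st <- network$strands[[i]]
    data.frame(strand = i, point = seq_len(nrow(st$points)),
               z_um = st$points[, 1], y_um = st$points[, 2],
               x_um = st$points[, 3], radius_um = st$radii_um,
               energy = st$energies)
  }))
  if (is.null(tr)) tr <- data.frame(strand = integer(), point = integer(),
                                    z_um = numeric(), y_um = numeric(),
                                    x_um = numeric(), radius_um = numeric(),
                                    energy = numeric())
  utils::write.csv(tr, path, row.names = FALSE)
  if (!is.null(summary_path)) {
    ids <- c(network$bifurcations, network$endpoints)
    summ <- data.frame(
      id = ids,
      role = rep(c("bifurcation", "endpoint"),
                 c(length(network$bifurcations), length(network$endpoints))))
    utils::write.csv(summ, summary_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write bulk statistics as a JSON summary
#'
#' @param stats a [bulk_stats()] object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Optional 3x3x3 median pre-filter
#'
#' Useful for salt-and-pepper artifacts in tiled acquisitions; boundaries
#' are mirrored.
#'
#' @param grid a [voxel_grid()].
#' @return The filtered [voxel_grid()].
#' @export
median_filter3 <- function(grid) {
  stopifnot_voxel_grid(grid)
  d <- dim(grid$values)
  voxel_grid(array(cpp_median3(as.numeric(grid$values), as.integer(d)), d),
             grid$spacing, grid$origin)
}
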