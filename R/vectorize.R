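#' Vectorize a vascular volume
#'
#' The top-level driver: multi-scale matched filtering, vertex extraction,
#' edge tracing, trace cleanup (mutual-discovery deduplication, small-cycle
#' removal), optional global energy-threshold classification, and network
#' identification with strand smoothing. Each stage's wall time is
#' recorded.
#'
#' @param image a [voxel_grid()], or a 3-D array (combined with `spacing`).
#' @param config a [pipeline_config()]; individual parameters can be
#'   overridden through `...`.
#' @param spacing voxel lengths (um) when `image` is a bare array.
#' @param ... overrides for single [pipeline_config()] fields.
#' @return Object of class `vessel_vectorization`: list with `fields`
#'   (energy/size), `vertices`, `edges` (post-cleanup), `network`
#'   (smoothed), `config`, `bank`, `timings` (seconds per stage).
#' @examples
#' \donttest{
#' net <- generate_phantom(phantom_spec(domain_um = c(48, 48, 48),
#'                                      n_trees = 1, n_branches = 0,
#'                                      seed = 7))
#' img <- simulate_image(render_binary(net, spacing = 2, supersample = 2),
#'                       sim_config(spacing_um = c(2, 2, 2), seed = 7))
#' fit <- vectorize_vessels(img, r_min_um = 2, r_max_um = 8)
#' print(fit)
#' }
#' @export
vectorize_vessels <- function(image, config = pipeline_config(...),
                              spacing = c(1, 1, 1), ...) {
  if (!inherits(image, "voxel_grid")) image <- voxel_grid(image, spacing)
  timings <- c()
  tic <- function() proc.time()[[3]]
  t0 <- tic()
  if (config$median_filter) image <- median_filter3(image)
  bank <- scale_bank(config$r_min_um, config$r_max_um,
                     config$scales_per_octave, f_G = config$f_G,
                     f_S = config$f_S, psf_std_um = config$psf_std_um)
  fields <- if (is.null(config$chunk_shape))
    energy_fields(image, bank)
  else filter_chunked(image, bank, config$chunk_shape,
                      config$max_voxels_per_radius)
  timings["energy"] <- tic() - t0; t0 <- tic()
  vertices <- extract_vertices(fields)
  if (!is.null(config$vertex_energy_max))
    vertices <- vertices[vertices$energy <= config$vertex_energy_max, ,
                         drop = FALSE]
  timings["vertices"] <- tic() - t0; t0 <- tic()
  limits <- extraction_limits(config$max_edges_per_vertex,
                              config$max_trace_factor)
  edges <- extract_edges(vertices, fields, limits)
  edges <- remove_small_cycles(vertices, deduplicate_mutual(edges))
  if (!is.null(config$edge_energy_max))
    edges <- edges[vapply(edges, `[[`, numeric(1), "max_energy") <=
                     config$edge_energy_max]
  timings["edges"] <- tic() - t0; t0 <- tic()
  network <- identify_network(vertices, edges, spacing = image$spacing,
                              origin = image$origin)
  network <- smooth_strands(network)
  attr(network, "domain_um") <- grid_extent(image)
  timings["network"] <- tic() - t0
  structure(list(fields = fields, vertices = vertices, edges = edges,
                 network = network, config = config, bank = bank,
                 image_dim = dim(image$values), spacing = image$spacing,
                 origin = image$origin, timings = timings),
            class = "vessel_vectorization")
}

#' @export
print.vessel_vectorization <- function(x, ...) {
  cat(sprintf(
    "<vessel_vectorization> %s voxels, %d vertices, %d edges\n",
    paste(x$image_dim, collapse = " x "), nrow(x$vertices),
    length(x$edges)))
  print(x$network)
  cat(sprintf("  stage times [s]: %s\n",
              paste(sprintf("%s %.1f", names(x$timings), x$timings),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.vessel_vectorization <- function(object, ...) {
  vol <- prod(object$image_dim * object$spacing) / 1e9
  bulk_stats(to_cylinders(object$network),
             length(object$network$bifurcations), vol)
}

#' @export
plot.vessel_vectorization <- function(x, mode = "strand", ...) {
  grid <- voxel_grid(array(0, x$image_dim), x$spacing, x$origin)
  img <- render_projections(x$network, grid, mode = mode)
  op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, 1, 1)
  invisible(img)
}
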