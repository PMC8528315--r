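#' Pipeline configuration
#'
#' All processing parameters of the vectorization pipeline in one
#' validated container that round-trips losslessly through JSON. Unknown
#' keys are rejected, both here and when reading a file.
#'
#' @param r_min_um,r_max_um matched-filter radius range (um).
#' @param scales_per_octave scale samples per volume doubling.
#' @param f_G Gaussian fraction in `[0, 1]`.
#' @param f_S spherical fraction in `[0, 1]`.
#' @param psf_std_um per-axis PSF standard deviation (um).
#' @param spacing_um per-axis voxel length (um).
#' @param chunk_shape optional chunk dimensions (voxels) for
#'   [filter_chunked()]; `NULL` filters in one chunk.
#' @param max_voxels_per_radius downsampling trigger (voxels per matched
#'   radius).
#' @param max_edges_per_vertex,max_trace_factor see [extraction_limits()].
#' @param median_filter apply the 3x3x3 median pre-filter.
#' @param vertex_energy_max,edge_energy_max optional global classification
#'   thresholds (keep objects with energy feature at or below the value);
#'   `NULL` keeps everything.
#' @param seed integer seed for seeded stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(r_min_um = 1.5, r_max_um = 60,
                            scales_per_octave = 3L, f_G = 0.5, f_S = 1,
                            psf_std_um = c(0, 0, 0),
                            spacing_um = c(1, 1, 1), chunk_shape = NULL,
                            max_voxels_per_radius = 10,
                            max_edges_per_vertex = 4L,
                            max_trace_factor = 30,
                            median_filter = FALSE,
                            vertex_energy_max = NULL,
                            edge_energy_max = NULL, seed = 1L) {
  cfg <- list(r_min_um = as.numeric(r_min_um),
              r_max_um = as.numeric(r_max_um),
              scales_per_octave = as.integer(scales_per_octave),
              f_G = as.numeric(f_G), f_S = as.numeric(f_S),
              psf_std_um = as.numeric(psf_std_um),
              spacing_um = as.numeric(spacing_um),
              chunk_shape = if (!is.null(chunk_shape))
                as.integer(chunk_shape),
              max_voxels_per_radius = as.numeric(max_voxels_per_radius),
              max_edges_per_vertex = as.integer(max_edges_per_vertex),
              max_trace_factor = as.numeric(max_trace_factor),
              median_filter = isTRUE(median_filter),
              vertex_energy_max = if (!is.null(vertex_energy_max))
                as.numeric(vertex_energy_max),
              edge_energy_max = if (!is.null(edge_energy_max))
                as.numeric(edge_energy_max),
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

config_keys <- function() names(formals(pipeline_config))

validate_config <- function(cfg) {
  plan_scales(cfg$r_min_um, cfg$r_max_um, cfg$scales_per_octave)
  if (cfg$f_G < 0 || cfg$f_G > 1 || cfg$f_S < 0 || cfg$f_S > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (any(cfg$spacing_um <= 0) || length(cfg$spacing_um) != 3L)
    stop("`spacing_um` must be 3 positive lengths", call. = FALSE)
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(Filter(Negate(is.null), unclass(config)), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) if (!is.null(x[[k]]))
    cat(sprintf("  %-22s %s\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}
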