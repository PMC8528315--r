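## Automated vector classification by energy thresholding, and evaluation
## of vectorization performance against a ground-truth mask.

# positions (um, relative to the grid origin), radii and object grouping of
# renderable objects: a vertex data frame, an edge list, or a network
object_points <- function(objects, grid) {
  if (is.data.frame(objects)) {
    centers <- cbind(objects$z_um, objects$y_um, objects$x_um)
    centers <- sweep(centers, 2L, grid$origin, "-")
    list(centers = centers, radii = objects$radius_um,
         group = seq_len(nrow(objects)), n = nrow(objects))
  } else if (inherits(objects, "vessel_network")) {
    pts <- do.call(rbind, lapply(objects$strands, `[[`, "points"))
    radii <- unlist(lapply(objects$strands, `[[`, "radii_um"))
    grp <- rep(seq_along(objects$strands),
               vapply(objects$strands, function(s) nrow(s$points),
                      integer(1)))
    list(centers = sweep(pts, 2L, grid$origin, "-"), radii = radii,
         group = grp, n = length(objects$strands))
  } else { # edge list
    pts <- do.call(rbind, lapply(objects, function(e)
      sweep(sweep(e$trace - 1, 2L, grid$spacing, "*"),
            2L, grid$origin - grid$origin, "+")))
    radii <- unlist(lapply(objects, `[[`, "radii_um"))
    grp <- rep(seq_along(objects),
               vapply(objects, function(e) nrow(e$trace), integer(1)))
    list(centers = pts, radii = radii, group = grp, n = length(objects))
  }
}

#' Render vector objects as a binary mask
#'
#' Volume filling places anisotropy-aware balls of (scaled) estimated
#' radius concentric with the centerline points; centerline filling marks
#' only the nearest voxel of each centerline point.
#'
#' @param objects a vertex data frame, an edge list, or a
#'   `vessel_network`.
#' @param grid a [voxel_grid()] defining the target raster.
#' @param fill `"volume"` or `"centerline"`.
#' @param radius_scale multiplier on the estimated radii (e.g. 0.25 renders
#'   at a quarter radius for overlays).
#' @return A binary (0/1) [voxel_grid()].
#' @export
render_mask <- function(objects, grid, fill = c("volume", "centerline"),
                        radius_scale = 1) {
  fill <- match.arg(fill)
  d <- dim(grid$values)
  op <- object_points(objects, grid)
  if (op$n == 0L || nrow(op$centers) == 0L)
    return(voxel_grid(array(0, d), grid$spacing, grid$origin))
  if (fill == "volume") {
    mask <- cpp_stamp_balls(op$centers, op$radii, as.integer(d),
                            grid$spacing, radius_scale)
  } else {
    idx <- round(sweep(op$centers, 2L, grid$spacing, "/")) + 1
    ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
      idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
    mask <- logical(prod(d))
    lin <- idx[ok, 1] + (idx[ok, 2] - 1) * d[1] +
      (idx[ok, 3] - 1) * d[1] * d[2]
    mask[lin] <- TRUE
  }
  voxel_grid(array(as.numeric(mask), d), grid$spacing, grid$origin)
}

confusion_row <- function(TP, FP, TN, FN) {
  total <- TP + FP + TN + FN
  data.frame(TP = TP, FP = FP, TN = TN, FN = FN,
             sensitivity = ifelse(TP + FN > 0, TP / (TP + FN), NA_real_),
             specificity = ifelse(TN + FP > 0, TN / (TN + FP), NA_real_),
             accuracy = (TP + TN) / total)
}

#' Sweep an energy threshold over vector objects against ground truth
#'
#' Objects are retained when their energy feature (vertex energy, or edge
#' maximum energy) lies at or below the threshold; the retained set is
#' volume-rendered and compared voxel-by-voxel with the truth mask. Every
#' distinct feature value (plus minus infinity, the empty set) is a
#' candidate threshold; the confusion table is accumulated incrementally so
#' the sweep costs one rendering pass. The best operating point maximizes
#' classification accuracy, ties resolved toward the stricter (more
#' negative) threshold.
#'
#' @param objects vertex data frame or edge list.
#' @param truth binary ground-truth [voxel_grid()].
#' @param grid the raster to render on (defaults to `truth`).
#' @param feature energy feature values, one per object; defaults to vertex
#'   `energy` or edge `max_energy`.
#' @param radius_scale radius multiplier for rendering.
#' @return List of class `roc_sweep`: `roc` (data frame of threshold,
#'   confusion counts, sensitivity, specificity, accuracy, ordered from
#'   strict to loose), `best` (row of the maximal-accuracy operating
#'   point), `keep_best` (logical per object).
#' @export
threshold_sweep <- function(objects, truth, grid = truth, feature = NULL,
                            radius_scale = 1) {
  if (is.null(feature)) {
    feature <- if (is.data.frame(objects)) objects$energy
    else vapply(objects, `[[`, numeric(1), "max_energy")
  }
  n_obj <- length(feature)
  d <- dim(truth$values)
  tr <- as.logical(truth$values > 0.5)
  n_total <- length(tr)
  n_fg <- sum(tr)
  op <- object_points(objects, grid)
  vox <- if (n_obj > 0L)
    cpp_ball_voxel_lists(op$centers, op$radii, as.integer(op$group),
                         n_obj, as.integer(d), grid$spacing, radius_scale)
  else list()
  ord <- order(feature)
  cover <- integer(n_total)
  TP <- 0L; FP <- 0L
  thr <- c(-Inf, feature[ord])
  tp_v <- fp_v <- numeric(n_obj + 1L)
  tp_v[1] <- 0; fp_v[1] <- 0
  for (k in seq_len(n_obj)) {
    vi <- vox[[ord[k]]]
    if (length(vi)) {
      new <- vi[cover[vi] == 0L]
      cover[vi] <- cover[vi] + 1L
      TP <- TP + sum(tr[new])
      FP <- FP + (length(new) - sum(tr[new]))
    }
    tp_v[k + 1L] <- TP; fp_v[k + 1L] <- FP
  }
  ## collapse duplicate thresholds to the loosest (last) occurrence
  keep_row <- c(TRUE, !duplicated(thr[-1], fromLast = TRUE))
  roc <- cbind(data.frame(threshold = thr[keep_row]),
               confusion_row(tp_v[keep_row], fp_v[keep_row],
                             n_total - n_fg - fp_v[keep_row],
                             n_fg - tp_v[keep_row]))
  ibest <- which.max(roc$accuracy)
  best <- roc[ibest, , drop = FALSE]
  keep_best <- feature <= best$threshold
  structure(list(roc = roc, best = best, keep_best = keep_best),
            class = "roc_sweep")
}

#' @export
print.roc_sweep <- function(x, ...) {
  cat(sprintf(
    "<roc_sweep> %d operating points; best accuracy %.4f at threshold %.4g (keeps %d objects)\n",
    nrow(x$roc), x$best$accuracy, x$best$threshold, sum(x$keep_best)))
  invisible(x)
}

#' Voxel-intensity thresholding benchmark
#'
#' The conventional segmentation baseline: classify a voxel foreground when
#' its intensity is at or above a threshold, sweeping (a subsample of) the
#' distinct intensities.
#'
#' @param image intensity [voxel_grid()].
#' @param truth binary ground-truth [voxel_grid()].
#' @param max_thresholds cap on the number of candidate thresholds
#'   (quantile-subsampled; default 512).
#' @return A `roc_sweep`-like list with `roc` and `best`.
#' @export
intensity_sweep <- function(image, truth, max_thresholds = 512L) {
  I <- as.numeric(image$values)
  tr <- as.logical(truth$values > 0.5)
  n <- length(I)
  n_fg <- sum(tr)
  tv <- sort(unique(I))
  if (length(tv) > max_thresholds)
    tv <- unique(stats::quantile(tv, seq(0, 1, length.out = max_thresholds),
                                 names = FALSE, type = 1))
  tv <- c(tv, Inf) # Inf = empty foreground
  si <- sort(I)
  truth_by_I <- cumsum(tr[order(I)])
  below <- findInterval(tv, si, left.open = TRUE) # #voxels with I < t
  fg_below <- ifelse(below > 0, truth_by_I[pmax(below, 1L)], 0)
  fg_below[below == 0] <- 0
  TP <- n_fg - fg_below
  FP <- (n - below) - TP
  roc <- cbind(data.frame(threshold = tv),
               confusion_row(TP, FP, n - n_fg - FP, n_fg - TP))
  roc <- roc[order(-roc$threshold), ] # strict (empty) to loose
  rownames(roc) <- NULL
  ibest <- which.max(roc$accuracy)
  structure(list(roc = roc, best = roc[ibest, , drop = FALSE]),
            class = "roc_sweep")
}

#' Signed percent errors of bulk statistics
#'
#' @param measured,truth [bulk_stats()] objects; truth totals must be
#'   positive.
#' @return Named numeric vector of `100 * (measured - truth) / truth` for
#'   volume, lateral area, length and bifurcation count.
#' @export
stat_percent_errors <- function(measured, truth) {
  tv <- c(volume = truth$volume_mm3, area = truth$area_mm2,
          length = truth$length_mm, bifurcations = truth$n_bifurcations)
  if (any(tv <= 0)) stop("truth totals must be positive", call. = FALSE)
  mv <- c(volume = measured$volume_mm3, area = measured$area_mm2,
          length = measured$length_mm,
          bifurcations = measured$n_bifurcations)
  100 * (mv - tv) / tv
}

#' Fully-automated vectorization and evaluation of one image
#'
#' Runs the complete automated pipeline on one (typically simulated) image
#' with known ground truth: energy filtering, vertex extraction, a vertex
#' energy-threshold sweep whose maximal-accuracy set seeds edge extraction,
#' an edge maximum-energy sweep, network identification and bulk
#' statistics, plus the voxel-intensity benchmark.
#'
#' @param image intensity [voxel_grid()].
#' @param params list of processing parameters: `r_min`, `r_max`,
#'   `scales_per_octave`, `f_G`, `f_S`, `psf_std_um`, optional `limits`
#'   ([extraction_limits()]).
#' @param truth binary ground-truth [voxel_grid()] on the image raster.
#' @param truth_stats [bulk_stats()] of the ground-truth network, or NULL
#'   to skip percent errors.
#' @return List of class `pipeline_report`: vertex and edge `roc_sweep`s,
#'   the surviving network, measured `bulk_stats`, `percent_errors`,
#'   `intensity` benchmark sweep, and the best accuracies.
#' @export
run_automated_pipeline <- function(image, params, truth,
                                   truth_stats = NULL) {
  limits <- params$limits
  if (is.null(limits)) limits <- extraction_limits()
  bank <- scale_bank(params$r_min, params$r_max, params$scales_per_octave,
                     f_G = params$f_G, f_S = params$f_S,
                     psf_std_um = if (is.null(params$psf_std_um)) 0
                     else params$psf_std_um)
  fields <- energy_fields(image, bank)
  vertices <- extract_vertices(fields)
  vsweep <- threshold_sweep(vertices, truth, image)
  vkeep <- vertices[vsweep$keep_best, , drop = FALSE]
  edges <- extract_edges(vkeep, fields, limits)
  edges <- remove_small_cycles(vkeep, deduplicate_mutual(edges))
  esweep <- threshold_sweep(edges, truth, image)
  ekeep <- edges[esweep$keep_best]
  network <- identify_network(vkeep, ekeep, spacing = image$spacing,
                              origin = image$origin)
  network <- smooth_strands(network)
  vol_mm3 <- prod(grid_extent(image)) / 1e9
  measured <- bulk_stats(to_cylinders(network),
                         length(network$bifurcations), vol_mm3)
  ibench <- intensity_sweep(image, truth)
  report <- list(
    vertex_sweep = vsweep, edge_sweep = esweep,
    network = network, measured_stats = measured,
    intensity = ibench,
    best_vertex_accuracy = vsweep$best$accuracy,
    best_edge_accuracy = esweep$best$accuracy,
    best_intensity_accuracy = ibench$best$accuracy,
    n_vertices = nrow(vertices), n_vertices_kept = nrow(vkeep),
    n_edges_kept = length(ekeep))
  if (!is.null(truth_stats))
    report$percent_errors <- stat_percent_errors(measured, truth_stats)
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    paste0("<pipeline_report> accuracies: vertices %.4f, edges %.4f, ",
           "intensity benchmark %.4f\n"),
    x$best_vertex_accuracy, x$best_edge_accuracy,
    x$best_intensity_accuracy))
  if (!is.null(x$percent_errors)) {
    cat("  percent errors: ")
    cat(paste(sprintf("%s %+.1f%%", names(x$percent_errors),
                      x$percent_errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Image-quality sweep of fully-automated vectorization
#'
#' The evaluation protocol for simulated two-photon images: generate a
#' seeded ground-truth phantom, render its binary truth, simulate one image
#' per requested contrast-to-noise ratio (background intensity fixed,
#' foreground solved for the target CNR), and run
#' [run_automated_pipeline()] on each.
#'
#' @param cnrs numeric vector of contrast-to-noise ratios to simulate.
#' @param spec a [phantom_spec()] describing the ground-truth network.
#' @param params processing parameters (see [run_automated_pipeline()]).
#' @param I_B background intensity of the simulator.
#' @param psf_std_um simulator PSF standard deviations (um).
#' @param supersample rendering supersampling factor.
#' @param spacing_um image voxel lengths (um).
#' @param seed seed for the noise draws (one offset per CNR).
#' @return List with the phantom `network`, `truth_stats`, and `reports`
#'   (one `pipeline_report` per CNR, named by CNR).
#' @export
quality_sweep <- function(cnrs, spec, params, I_B = 25,
                          psf_std_um = c(1.5, 0.7, 0.7), supersample = 2L,
                          spacing_um = c(1, 1, 1), seed = 1L) {
  net <- generate_phantom(spec)
  binary <- render_binary(net, spacing = spacing_um,
                          supersample = supersample)
  truth <- render_binary(net, spacing = spacing_um, supersample = 1L)
  vol_mm3 <- prod(spec$domain_um) / 1e9
  truth_stats <- bulk_stats(to_cylinders(net), length(net$bifurcations),
                            vol_mm3)
  reports <- lapply(seq_along(cnrs), function(i) {
    ii <- intensities_for_cnr(cnrs[i], I_B)
    cfg <- sim_config(I_F = ii$I_F, I_B = ii$I_B, psf_std_um = psf_std_um,
                      supersample = supersample, spacing_um = spacing_um,
                      seed = seed + i)
    img <- simulate_image(binary, cfg)
    run_automated_pipeline(img, params, truth, truth_stats)
  })
  names(reports) <- as.character(cnrs)
  list(network = net, truth_stats = truth_stats, reports = reports)
}
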