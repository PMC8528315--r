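#' Consecutive-cylinder idealization of a network
#'
#' Each strand is idealized as a chain of right circular cylinders joined
#' face to face: one cylinder per consecutive point pair, with radius the
#' arithmetic mean of the two point radii, height the chord length, and
#' inclination the angle of the chord from the xy plane
#' (`asin(|dz| / height)`, degrees). Zero-height cylinders (coincident
#' consecutive points) are dropped.
#'
#' @param network a `vessel_network` (strand points in um).
#' @return Data frame of cylinders: `strand`, endpoint coordinates
#'   (`z0,y0,x0,z1,y1,x1`, um), `radius_um`, `height_um`,
#'   `lateral_area_um2` (`2*pi*r*h`), `volume_um3` (`pi*r^2*h`),
#'   `inclination_deg` in `[0, 90]`, `depth_um` (mean z of the endpoints).
#' @export
to_cylinders <- function(network) {
  rows <- lapply(seq_along(network$strands), function(si) {
    st <- network$strands[[si]]
    n <- nrow(st$points)
    if (n < 2L) return(NULL)
    p0 <- st$points[-n, , drop = FALSE]
    p1 <- st$points[-1, , drop = FALSE]
    h <- sqrt(rowSums((p1 - p0)^2))
    keep <- h > 0
    if (!any(keep)) return(NULL)
    r <- (st$radii_um[-n] + st$radii_um[-1])[keep] / 2
    p0 <- p0[keep, , drop = FALSE]; p1 <- p1[keep, , drop = FALSE]
    h <- h[keep]
    data.frame(strand = si,
               z0 = p0[, 1], y0 = p0[, 2], x0 = p0[, 3],
               z1 = p1[, 1], y1 = p1[, 2], x1 = p1[, 3],
               radius_um = r, height_um = h,
               lateral_area_um2 = 2 * pi * r * h,
               volume_um3 = pi * r^2 * h,
               inclination_deg = asin(pmin(abs(p1[, 1] - p0[, 1]) / h, 1)) *
                 180 / pi,
               depth_um = (p0[, 1] + p1[, 1]) / 2)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- to_cylinders_empty()
  out
}

to_cylinders_empty <- function() {
  data.frame(strand = integer(), z0 = numeric(), y0 = numeric(),
             x0 = numeric(), z1 = numeric(), y1 = numeric(), x1 = numeric(),
             radius_um = numeric(), height_um = numeric(),
             lateral_area_um2 = numeric(), volume_um3 = numeric(),
             inclination_deg = numeric(), depth_um = numeric())
}

#' Bulk network statistics and densities
#'
#' Sums cylinder heights, lateral areas and volumes (converted to mm-based
#' units) and divides by the imaged volume to obtain the densities commonly
#' reported for cortical microvasculature: length density (m/mm^3), surface
#' area density (mm^2/mm^3), volume fraction, and bifurcation density
#' (1/mm^3).
#'
#' @param cylinders data frame from [to_cylinders()].
#' @param n_bifurcations bifurcation count of the network.
#' @param image_volume_mm3 imaged tissue volume (mm^3), positive.
#' @return List of class `bulk_stats`: totals `length_mm`, `area_mm2`,
#'   `volume_mm3`, `n_bifurcations`, and densities `length_density_m_mm3`,
#'   `area_density_mm2_mm3`, `volume_fraction`,
#'   `bifurcation_density_mm3`, plus `image_volume_mm3`.
#' @export
bulk_stats <- function(cylinders, n_bifurcations, image_volume_mm3) {
  bulk_stats_from_totals(
    length_mm = sum(cylinders$height_um) / 1e3,
    area_mm2 = sum(cylinders$lateral_area_um2) / 1e6,
    volume_mm3 = sum(cylinders$volume_um3) / 1e9,
    n_bifurcations = n_bifurcations,
    image_volume_mm3 = image_volume_mm3)
}

#' @rdname bulk_stats
#' @param length_mm,area_mm2,volume_mm3 pre-computed totals, for deriving
#'   densities from published tables without re-tracing the network.
#' @export
bulk_stats_from_totals <- function(length_mm, area_mm2, volume_mm3,
                                   n_bifurcations, image_volume_mm3) {
  if (!is.finite(image_volume_mm3) || image_volume_mm3 <= 0)
    stop("`image_volume_mm3` must be positive", call. = FALSE)
  structure(list(
    length_mm = length_mm, area_mm2 = area_mm2, volume_mm3 = volume_mm3,
    n_bifurcations = n_bifurcations,
    image_volume_mm3 = image_volume_mm3,
    length_density_m_mm3 = (length_mm / 1e3) / image_volume_mm3,
    area_density_mm2_mm3 = area_mm2 / image_volume_mm3,
    volume_fraction = volume_mm3 / image_volume_mm3,
    bifurcation_density_mm3 = n_bifurcations / image_volume_mm3),
    class = "bulk_stats")
}

#' @export
print.bulk_stats <- function(x, ...) {
  cat(sprintf(
    paste0("<bulk_stats> length %.3g mm, area %.3g mm2, volume %.3g mm3, ",
           "%d bifurcations\n  length density %.3g m/mm3, volume fraction ",
           "%.3g, bifurcation density %.3g /mm3\n"),
    x$length_mm, x$area_mm2, x$volume_mm3, round(x$n_bifurcations),
    x$length_density_m_mm3, x$volume_fraction, x$bifurcation_density_mm3))
  invisible(x)
}

#' Lateral-area-weighted histogram of a cylinder quantity
#'
#' Histograms of vessel depth, radius or inclination are weighted by the
#' cylinder lateral surface area, the anatomically relevant weight because
#' lateral area is proportional to trans-wall chemical flux.
#'
#' @param cylinders data frame from [to_cylinders()].
#' @param quantity one of `"depth"`, `"radius"`, `"inclination"`.
#' @param breaks increasing bin edges covering the data range.
#' @return Data frame with `lower`, `upper` bin edges and `mass` (sum of
#'   lateral areas, um^2); total mass equals the total lateral area.
#' @export
weighted_histogram <- function(cylinders,
                               quantity = c("depth", "radius",
                                            "inclination"),
                               breaks) {
  quantity <- match.arg(quantity)
  v <- switch(quantity, depth = cylinders$depth_um,
              radius = cylinders$radius_um,
              inclination = cylinders$inclination_deg)
  if (length(v) && (any(v < breaks[1]) || any(v > breaks[length(breaks)])))
    stop("`breaks` must cover the data range", call. = FALSE)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- length(breaks) - 1L
  mass <- vapply(seq_len(nb), function(b)
    sum(cylinders$lateral_area_um2[bin == b]), numeric(1))
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             mass = mass)
}

#' Depth-resolved vascular densities
#'
#' Cylinders are binned by the depth of their midpoint; per bin, summed
#' heights, lateral areas and volumes are divided by the tissue volume
#' apportioned to the bin (cross-section area times bin thickness), and
#' mean radius and inclination are lateral-area-weighted averages.
#'
#' @param cylinders data frame from [to_cylinders()].
#' @param breaks increasing z bin edges (um) partitioning the imaged depth.
#' @param cross_section_um2 image cross-section area (um^2) perpendicular
#'   to z.
#' @return Data frame per bin: `lower`, `upper` (um),
#'   `length_density_m_mm3`, `area_density_mm2_mm3`, `volume_fraction`,
#'   `mean_radius_um`, `mean_inclination_deg` (the means are `NA` for empty
#'   bins).
#' @export
depth_profile <- function(cylinders, breaks, cross_section_um2) {
  nb <- length(breaks) - 1L
  bin <- findInterval(cylinders$depth_um, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- lapply(seq_len(nb), function(b) {
    cyl <- cylinders[bin == b, , drop = FALSE]
    vol_mm3 <- cross_section_um2 * (breaks[b + 1] - breaks[b]) / 1e9
    A <- sum(cyl$lateral_area_um2)
    data.frame(
      lower = breaks[b], upper = breaks[b + 1],
      length_density_m_mm3 = (sum(cyl$height_um) / 1e9) / vol_mm3 * 1e3,
      area_density_mm2_mm3 = (A / 1e6) / vol_mm3,
      volume_fraction = (sum(cyl$volume_um3) / 1e9) / vol_mm3,
      mean_radius_um = if (A > 0) sum(cyl$radius_um *
                                        cyl$lateral_area_um2) / A else NA_real_,
      mean_inclination_deg = if (A > 0) sum(cyl$inclination_deg *
                                              cyl$lateral_area_um2) / A
      else NA_real_)
  })
  do.call(rbind, out)
}
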