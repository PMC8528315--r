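two_point_network <- function(p0, p1, r0, r1 = r0) {
  structure(list(strands = list(list(
    points = rbind(p0, p1), radii_um = c(r0, r1), energies = c(-1, -1),
    end_vertices = c(1L, 2L), n_edges = 1L)),
    bifurcations = integer(), endpoints = c(1L, 2L), vertices = NULL,
    n_edges = 1L), class = "vessel_network")
}

test_that("single cylinders reproduce the closed forms exactly", {
  ## horizontal cylinder: r = 2, h = 100 -> area and volume both 400*pi
  cyl <- to_cylinders(two_point_network(c(0, 0, 0), c(0, 0, 100), 2))
  expect_identical(nrow(cyl), 1L)
  expect_equal(cyl$lateral_area_um2, 400 * pi, tolerance = 1e-9)
  expect_equal(cyl$volume_um3, 400 * pi, tolerance = 1e-9)
  expect_equal(cyl$inclination_deg, 0)
  expect_equal(cyl$height_um, 100)

  vert <- to_cylinders(two_point_network(c(0, 0, 0), c(50, 0, 0), 2))
  expect_equal(vert$inclination_deg, 90)

  ## 3-point right angle, unit radii: two unit cylinders
  nw <- two_point_network(c(0, 0, 0), c(0, 0, 10), 1)
  nw$strands[[1]]$points <- rbind(c(0, 0, 0), c(0, 0, 10), c(10, 0, 10))
  nw$strands[[1]]$radii_um <- c(1, 1, 1)
  nw$strands[[1]]$energies <- rep(-1, 3)
  cyl <- to_cylinders(nw)
  expect_identical(nrow(cyl), 2L)
  expect_equal(sum(cyl$height_um), 20)
  expect_equal(sum(cyl$lateral_area_um2), 2 * 2 * pi * 10, tolerance = 1e-9)
  expect_equal(sum(cyl$volume_um3), 2 * pi * 10, tolerance = 1e-9)
  expect_equal(cyl$inclination_deg, c(0, 90))

  ## zero-height cylinders are dropped
  nw$strands[[1]]$points <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 10))
  expect_identical(nrow(to_cylinders(nw)), 1L)
})

to_cylinders_empty_proxy <- function() {
  nw <- structure(list(strands = list(), bifurcations = integer(),
                       endpoints = integer(), vertices = NULL,
                       n_edges = 0L), class = "vessel_network")
  to_cylinders(nw)
}

test_that("bulk densities reproduce the published cortical values", {
  ## printed totals for the large tiled volume: 443 mm length and
  ## 4.40e-2 mm^3 vessel volume in 0.761 mm^3 of imaged tissue
  bs <- bulk_stats_from_totals(length_mm = 443, area_mm2 = 13.0,
                               volume_mm3 = 4.40e-2, n_bifurcations = 3383,
                               image_volume_mm3 = 0.761)
  expect_equal(round(bs$length_density_m_mm3, 1), 0.6)
  expect_equal(round(100 * bs$volume_fraction), 6)

  empty <- bulk_stats(to_cylinders_empty_proxy(), 0, 1)
  expect_equal(empty$length_mm, 0)
  expect_equal(empty$volume_mm3, 0)
  expect_equal(empty$area_mm2, 0)
})

test_that("lateral-area weighting places and conserves histogram mass", {
  nw <- two_point_network(c(0, 0, 0), c(0, 0, 100), 2)
  cyl <- to_cylinders(nw)
  h <- weighted_histogram(cyl, "inclination", breaks = c(0, 30, 60, 90))
  expect_equal(h$mass, c(400 * pi, 0, 0))

  cyl2 <- rbind(cyl, cyl)
  cyl2$radius_um <- c(2, 6)
  cyl2$lateral_area_um2 <- c(100, 300)
  h <- weighted_histogram(cyl2, "radius", breaks = c(0, 4, 8))
  expect_equal(h$mass, c(100, 300))

  set.seed(5)
  cyl2 <- cyl[rep(1, 20), ]
  cyl2$radius_um <- runif(20, 0.5, 7.5)
  cyl2$lateral_area_um2 <- runif(20, 1, 50)
  h <- weighted_histogram(cyl2, "radius", breaks = seq(0, 8, by = 1))
  expect_equal(sum(h$mass), sum(cyl2$lateral_area_um2))
  expect_error(weighted_histogram(cyl2, "radius", breaks = c(0, 1)),
               "cover")
})

test_that("depth profiles apportion densities bin by bin", {
  ## vertical vessel spanning two equal bins: equal length density
  nw <- two_point_network(c(0, 0, 0), c(100, 0, 0), 2)
  nw$strands[[1]]$points <- cbind(seq(0, 100, by = 10), 0, 0)
  nw$strands[[1]]$radii_um <- rep(2, 11)
  nw$strands[[1]]$energies <- rep(-1, 11)
  cyl <- to_cylinders(nw)
  prof <- depth_profile(cyl, breaks = c(0, 50, 100),
                        cross_section_um2 = 100 * 100)
  expect_equal(prof$length_density_m_mm3[1], prof$length_density_m_mm3[2])
  expect_equal(prof$mean_radius_um, c(2, 2))

  ## single cylinder in one bin
  cyl1 <- to_cylinders(two_point_network(c(10, 0, 0), c(12, 0, 50), 3))
  prof <- depth_profile(cyl1, breaks = c(0, 25, 50), 100 * 100)
  expect_equal(prof$mean_radius_um[1], 3)
  expect_true(is.na(prof$mean_radius_um[2]))

  ## three bins, hand-computed apportionment by cylinder midpoint depth
  nw3 <- two_point_network(c(5, 0, 0), c(35, 0, 40), 1)
  nw3$strands[[1]]$points <- rbind(c(5, 0, 0), c(15, 0, 20), c(35, 0, 40))
  nw3$strands[[1]]$radii_um <- c(1, 1, 1)
  nw3$strands[[1]]$energies <- rep(-1, 3)
  cyl3 <- to_cylinders(nw3)
  prof <- depth_profile(cyl3, breaks = c(0, 12, 30, 40), 100 * 100)
  binvol <- 1e4 * c(12, 18, 10) / 1e9
  expect_equal(prof$length_density_m_mm3,
               c(cyl3$height_um[1], cyl3$height_um[2], 0) / 1e6 / binvol)
  ## conservation: sum of per-bin length x bin volume = total length
  expect_equal(sum(prof$length_density_m_mm3 * binvol) * 1e6,
               sum(cyl3$height_um))
})

test_that("statistics are covariant under uniform scaling", {
  nw <- two_point_network(c(1, 2, 3), c(11, 7, 9), 2, 3)
  nw$strands[[1]]$points <- rbind(c(1, 2, 3), c(11, 7, 9), c(14, 20, 9))
  nw$strands[[1]]$radii_um <- c(2, 3, 2.5)
  nw$strands[[1]]$energies <- rep(-1, 3)
  base <- to_cylinders(nw)
  s <- 2.5
  nws <- nw
  nws$strands[[1]]$points <- nw$strands[[1]]$points * s
  nws$strands[[1]]$radii_um <- nw$strands[[1]]$radii_um * s
  scaled <- to_cylinders(nws)
  expect_equal(sum(scaled$height_um), s * sum(base$height_um))
  expect_equal(sum(scaled$lateral_area_um2),
               s^2 * sum(base$lateral_area_um2))
  expect_equal(sum(scaled$volume_um3), s^3 * sum(base$volume_um3))
  expect_equal(scaled$inclination_deg, base$inclination_deg)
})
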