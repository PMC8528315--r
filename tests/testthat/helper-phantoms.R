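# Shared fixtures, all generated in code.

# solid bright sphere of radius a (um) centred in an n^3 grid
sphere_image <- function(n, a, spacing = c(1, 1, 1)) {
  ax <- lapply(1:3, function(k) ((1:n) - (n + 1) / 2) * spacing[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  voxel_grid(array(as.numeric(r2 <= a^2), c(n, n, n)), spacing)
}

# straight tube of radius a along the x axis, centred in z/y
tube_image <- function(dims, a, spacing = c(1, 1, 1)) {
  z <- ((1:dims[1]) - (dims[1] + 1) / 2) * spacing[1]
  y <- ((1:dims[2]) - (dims[2] + 1) / 2) * spacing[2]
  r2 <- outer(z^2, y^2, "+")
  arr <- array(0, dims)
  for (x in seq_len(dims[3])) arr[, , x] <- as.numeric(r2 <= a^2)
  voxel_grid(arr, spacing)
}

# hand-built straight-tube ground-truth network along x
tube_network <- function(radius = 3, x0 = 8, x1 = 88, zy = 20,
                         domain = c(2 * zy, 2 * zy, x1 + x0), step = 2) {
  pts <- cbind(zy, zy, seq(x0, x1, by = step))
  structure(list(
    strands = list(list(points = pts, radii_um = rep(radius, nrow(pts)),
                        energies = rep(-1, nrow(pts)),
                        end_vertices = c(1L, 2L), n_edges = 1L)),
    bifurcations = integer(), endpoints = c(1L, 2L),
    vertices = data.frame(id = 1:2, z_um = c(zy, zy), y_um = c(zy, zy),
                          x_um = c(x0, x1)),
    n_edges = 1L), class = "vessel_network", domain_um = domain)
}

# minimal energy_fields object from explicit energy/size arrays
fields_from_arrays <- function(energy, size, spacing = c(1, 1, 1)) {
  structure(list(energy = voxel_grid(energy, spacing),
                 size = voxel_grid(size, spacing),
                 bank = NULL), class = "energy_fields")
}

# bank stub with arbitrary radii (geometric banks come from scale_bank())
bank_stub <- function(R, f_S = 1) {
  structure(list(scales = data.frame(index = seq_along(R), R = R,
                                     sigma = R / sqrt(2),
                                     r_ideal = R / sqrt(2),
                                     sigma_eff_z = R / sqrt(2),
                                     sigma_eff_y = R / sqrt(2),
                                     sigma_eff_x = R / sqrt(2)),
                 f_G = 0.5, f_S = f_S, scales_per_octave = 1L,
                 psf_std_um = c(0, 0, 0)), class = "scale_bank")
}

# toy edge constructor for graph-level operations
toy_edge <- function(a, b, max_energy, n = 2L) {
  tr <- cbind(seq(2, 2 + n - 1), 2L, 2L)
  list(vertex_a = a, vertex_b = b, trace = tr,
       radii_um = rep(1, n), energies = rep(max_energy, n),
       max_energy = max_energy)
}

# brute-force reference for vertex extraction: enumerate 26-neighbourhood
# minima (lexicographic tie-break), sort by energy, greedily accept centres
# not inside previously accepted physical balls
oracle_vertices <- function(energy, size, spacing) {
  d <- dim(energy)
  is_min <- function(z, y, x) {
    e <- energy[z, y, x]
    if (e >= 0) return(FALSE)
    lin <- z + (y - 1) * d[1] + (x - 1) * d[1] * d[2]
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      z2 <- z + dz; y2 <- y + dy; x2 <- x + dx
      if (z2 < 1 || z2 > d[1] || y2 < 1 || y2 > d[2] ||
          x2 < 1 || x2 > d[3]) next
      e2 <- energy[z2, y2, x2]
      l2 <- z2 + (y2 - 1) * d[1] + (x2 - 1) * d[1] * d[2]
      if (e2 < e || (e2 == e && l2 < lin)) return(FALSE)
    }
    TRUE
  }
  cand <- NULL
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1]))
    if (is_min(z, y, x))
      cand <- rbind(cand, c(z, y, x, energy[z, y, x], size[z, y, x]))
  if (is.null(cand)) return(cand)
  lin <- cand[, 1] + (cand[, 2] - 1) * d[1] + (cand[, 3] - 1) * d[1] * d[2]
  cand <- cand[order(cand[, 4], lin), , drop = FALSE]
  acc <- NULL
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, 1:3] * spacing
    ok <- TRUE
    if (!is.null(acc)) for (j in seq_len(nrow(acc))) {
      q <- acc[j, 1:3] * spacing
      if (sqrt(sum((p - q)^2)) <= acc[j, 5]) { ok <- FALSE; break }
    }
    if (ok) acc <- rbind(acc, cand[i, ])
  }
  acc
}

# brute-force triangle enumeration on an edge list
count_triangles <- function(edges) {
  if (length(edges) < 3L) return(0L)
  a <- vapply(edges, `[[`, numeric(1), "vertex_a")
  b <- vapply(edges, `[[`, numeric(1), "vertex_b")
  ids <- sort(unique(c(a, b)))
  n <- length(ids)
  A <- matrix(FALSE, n, n)
  A[cbind(match(a, ids), match(b, ids))] <- TRUE
  A <- A | t(A)
  cnt <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (i < j && j < k && A[i, j] && A[j, k] && A[i, k]) cnt <- cnt + 1L
  cnt
}

# continuous-domain radial quadrature of the matched-filter response at the
# centre of a solid sphere of radius a (isotropic, no PSF): independent
# oracle for scale selection under the analytic spectrum
oracle_sphere_response <- function(R, a, f_G) {
  sph <- function(u) ifelse(u < 1e-4, 1 - u^2 / 10,
                            3 * (sin(u) - u * cos(u)) / u^3)
  t <- f_G / (1 - f_G)
  r <- R / sqrt(1 + t^2); s <- t * r
  k <- seq(1e-4, 60, length.out = 24001)
  f <- k^2 * (-s^2 * k^2) * exp(-s^2 * k^2 / 2) * sph(k * r) * sph(k * a)
  sum(f) * (k[2] - k[1])
}
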