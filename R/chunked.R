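## Chunked and resolution-adaptive filtering. Large volumes are processed in
## overlapping chunks (mirror-padded before the FFT so the circular
## convolution never wraps real data) and, for coarse scales, downsampled so
## that no axis resolves more than `max_voxels_per_radius` voxels per matched
## radius, then upsampled back with linear interpolation. The contract is
## equivalence with the unchunked full-resolution pipeline to interpolation
## tolerance.

# reflected (mirror, no edge repeat) index into 1..n for arbitrary integers
reflect_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  m <- (j - 1L) %% (2L * n - 2L)
  ifelse(m < n, m + 1L, 2L * n - 1L - m)
}

# block-average downsample by integer factors k (length 3); dims must be
# padded to multiples of k by the caller
block_downsample <- function(arr, k) {
  d <- dim(arr)
  for (a in 1:3) {
    if (k[a] == 1L) next
    arr <- aperm(arr, c(a, setdiff(1:3, a)))
    da <- dim(arr)
    arr <- array(arr, c(k[a], da[1] / k[a], da[2], da[3]))
    arr <- colMeans(arr, dims = 1)
    arr <- aperm(arr, order(c(a, setdiff(1:3, a))))
  }
  arr
}

# Catmull-Rom (cubic) upsample along each axis from a block-averaged grid
# (factor k) back to n_fine samples; coarse sample j sits at fine
# coordinate (j - 1) * k + (k + 1) / 2. Ends are clamped.
block_upsample <- function(arr, k, n_fine) {
  for (a in 1:3) {
    if (k[a] == 1L && dim(arr)[a] == n_fine[a]) next
    arr <- aperm(arr, c(a, setdiff(1:3, a)))
    da <- dim(arr)
    nc <- da[1]
    t <- (seq_len(n_fine[a]) - (k[a] + 1) / 2) / k[a] + 1
    t <- pmin(pmax(t, 1), nc)
    j0 <- pmin(pmax(floor(t), 1L), max(nc - 1L, 1L))
    w <- t - j0
    m <- matrix(arr, nrow = nc)
    cl <- function(j) pmin(pmax(j, 1L), nc)
    p0 <- m[cl(j0 - 1L), , drop = FALSE]
    p1 <- m[cl(j0), , drop = FALSE]
    p2 <- m[cl(j0 + 1L), , drop = FALSE]
    p3 <- m[cl(j0 + 2L), , drop = FALSE]
    up <- 0.5 * ((2 * p1) + (-p0 + p2) * w +
                   (2 * p0 - 5 * p1 + 4 * p2 - p3) * w^2 +
                   (-p0 + 3 * p1 - 3 * p2 + p3) * w^3)
    arr <- array(up, c(n_fine[a], da[2], da[3]))
    arr <- aperm(arr, order(c(a, setdiff(1:3, a))))
  }
  arr
}

# per-axis kernel support of the whole bank, in voxels
bank_support_voxels <- function(bank, spacing, nsig = 3) {
  sup <- sapply(seq_len(nrow(bank$scales)),
                function(i) kernel_support_um(bank, i, nsig))
  as.integer(ceiling(apply(matrix(sup, nrow = 3), 1L, max) / spacing))
}

#' Memory-bounded chunked multi-scale filtering
#'
#' Equivalent to [filter_multiscale()] + [project_scales()] but processes the
#' volume in overlapping chunks and optionally downsamples coarse scales.
#' Each chunk is mirror-padded by the overlap before the FFT, so no circular
#' wrap-around crosses real data; with sufficient overlap and no
#' downsampling, the result is independent of the chunk layout.
#'
#' @param image a [voxel_grid()].
#' @param bank a [scale_bank()].
#' @param chunk_shape integer length-3 chunk dimensions in voxels (default:
#'   whole volume, i.e. a single chunk).
#' @param max_voxels_per_radius downsampling trigger: a scale whose matched
#'   radius spans more than this many voxels on some axis is filtered at a
#'   block-averaged resolution and linearly upsampled afterwards. Default 10;
#'   `Inf` disables downsampling.
#' @param overlap per-axis chunk overlap in voxels. Default: the bank's
#'   kernel support with a 5-standard-deviation Gaussian tail. Must be at
#'   least the 3-standard-deviation kernel support on every axis.
#' @return An `energy_fields` object (see [project_scales()]).
#' @export
filter_chunked <- function(image, bank, chunk_shape = NULL,
                           max_voxels_per_radius = 10, overlap = NULL) {
  stopifnot_voxel_grid(image)
  d <- dim(image$values)
  spacing <- image$spacing
  if (is.null(chunk_shape)) chunk_shape <- d
  chunk_shape <- as.integer(pmin(chunk_shape, d))
  if (any(chunk_shape < 1L)) stop("invalid `chunk_shape`", call. = FALSE)
  req <- bank_support_voxels(bank, spacing, nsig = 3)
  if (is.null(overlap)) {
    overlap <- bank_support_voxels(bank, spacing, nsig = 5)
  } else {
    if (length(overlap) == 1L) overlap <- rep(overlap, 3L)
    overlap <- as.integer(overlap)
    if (any(overlap < req))
      stop(sprintf(
        "chunk overlap (%s voxels) is smaller than the kernel support (%s)",
        paste(overlap, collapse = ","), paste(req, collapse = ",")),
        call. = FALSE)
  }
  R <- bank$scales$R
  energy <- array(0, d)
  size <- array(0, d)
  starts <- lapply(1:3, function(a) seq(1L, d[a], by = chunk_shape[a]))
  for (z0 in starts[[1]]) for (y0 in starts[[2]]) for (x0 in starts[[3]]) {
    lo <- c(z0, y0, x0)
    hi <- pmin(lo + chunk_shape - 1L, d)
    idx <- lapply(1:3, function(a)
      reflect_index((lo[a] - overlap[a]):(hi[a] + overlap[a]), d[a]))
    sub <- image$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dp <- dim(sub)
    stack <- vector("list", length(R))
    for (i in seq_along(R)) {
      k <- pmax(1L, as.integer(ceiling(R[i] / (spacing * max_voxels_per_radius))))
      if (all(k == 1L)) {
        spec <- kernel_spectrum(bank, i, dp, spacing)
        stack[[i]] <- Re(stats::fft(stats::fft(sub) * spec,
                                    inverse = TRUE)) / prod(dp)
      } else {
        ## mirror-extend to a multiple of k, block-average, filter coarse,
        ## linearly upsample back
        dpad <- as.integer(ceiling(dp / k) * k)
        ext <- lapply(1:3, function(a) reflect_index(seq_len(dpad[a]), dp[a]))
        coarse <- block_downsample(
          sub[ext[[1]], ext[[2]], ext[[3]], drop = FALSE], k)
        dc <- dim(coarse)
        spec <- kernel_spectrum(bank, i, dc, spacing * k)
        ## compensate the block-average (box) pre-filter within the
        ## coarse band; the Gaussian cutoff keeps this well-conditioned
        for (a in 1:3) {
          if (k[a] == 1L) next
          kw <- fft_wavenumbers(dc[a], spacing[a] * k[a]) * k[a] *
            spacing[a] / 2
          box <- ifelse(abs(kw) < 1e-12, 1, sin(kw) / kw)
          shape <- c(dc[a], dc[setdiff(1:3, a)])
          spec <- spec / aperm(array(box, shape),
                               order(c(a, setdiff(1:3, a))))
        }
        ec <- Re(stats::fft(stats::fft(coarse) * spec,
                            inverse = TRUE)) / prod(dc)
        stack[[i]] <- block_upsample(ec, k, dp)
      }
    }
    attr(stack, "spacing") <- spacing
    attr(stack, "origin") <- image$origin
    class(stack) <- "energy_stack"
    pr <- project_scales(stack, bank)
    cz <- (overlap[1] + 1):(overlap[1] + hi[1] - lo[1] + 1)
    cy <- (overlap[2] + 1):(overlap[2] + hi[2] - lo[2] + 1)
    cx <- (overlap[3] + 1):(overlap[3] + hi[3] - lo[3] + 1)
    energy[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      pr$energy$values[cz, cy, cx]
    size[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      pr$size$values[cz, cy, cx]
  }
  structure(list(
    energy = voxel_grid(energy, spacing, image$origin),
    size = voxel_grid(size, spacing, image$origin),
    bank = bank), class = "energy_fields")
}
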