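#' Two-photon image simulation settings
#'
#' Foreground/background intensities, PSF model and sampling of the
#' simulator. Contrast is `I_F - I_B`; noise is the standard deviation of
#' that difference under the Poisson-surrogate model, `sqrt(I_F + I_B)`;
#' their ratio is the contrast-to-noise ratio (CNR) summarizing image
#' quality.
#'
#' @param I_F foreground (intravascular) intensity; must exceed `I_B`.
#' @param I_B background intensity, positive.
#' @param psf_std_um per-axis Gaussian PSF standard deviation (um).
#' @param supersample integer factor: the ground truth is rendered at
#'   `spacing / supersample` and block-averaged back after blurring,
#'   modelling detector integration.
#' @param spacing_um target (output) voxel lengths (um).
#' @param seed integer seed for the noise draw.
#' @return List of class `sim_config` with a derived `cnr` field.
#' @export
sim_config <- function(I_F = 100, I_B = 25, psf_std_um = c(1.5, 0.7, 0.7),
                       supersample = 2L, spacing_um = c(1, 1, 1),
                       seed = 1L) {
  if (!(I_F > I_B && I_B > 0))
    stop("need I_F > I_B > 0", call. = FALSE)
  if (supersample < 1L) stop("`supersample` must be >= 1", call. = FALSE)
  if (length(psf_std_um) == 1L) psf_std_um <- rep(psf_std_um, 3L)
  if (length(spacing_um) == 1L) spacing_um <- rep(spacing_um, 3L)
  structure(list(I_F = I_F, I_B = I_B,
                 psf_std_um = as.numeric(psf_std_um),
                 supersample = as.integer(supersample),
                 spacing_um = as.numeric(spacing_um),
                 seed = as.integer(seed),
                 cnr = (I_F - I_B) / sqrt(I_F + I_B)),
            class = "sim_config")
}

#' Intensities achieving a target contrast-to-noise ratio
#'
#' Solves `(I_F - I_B) / sqrt(I_F + I_B) = cnr` for the foreground at a
#' fixed background.
#'
#' @param cnr target contrast-to-noise ratio.
#' @param I_B background intensity.
#' @return Named list with `I_F` and `I_B`.
#' @export
intensities_for_cnr <- function(cnr, I_B = 25) {
  contrast <- (cnr^2 + sqrt(cnr^4 + 8 * I_B * cnr^2)) / 2
  list(I_F = I_B + contrast, I_B = I_B)
}

#' Render a network as a binary volume fill
#'
#' A voxel is foreground iff it lies within the (linearly interpolated)
#' radius of some strand centerline segment; rendering is anisotropy-aware
#' and monotone in radius (dilating all radii never unsets a voxel).
#'
#' @param network a `vessel_network` with strand points in um.
#' @param spacing target voxel lengths (um).
#' @param supersample integer factor; the returned grid has spacing
#'   `spacing / supersample`.
#' @param domain_um physical domain (um); defaults to the network's
#'   `domain_um` attribute.
#' @return A binary (0/1) [voxel_grid()].
#' @export
render_binary <- function(network, spacing = c(1, 1, 1), supersample = 1L,
                          domain_um = attr(network, "domain_um")) {
  if (is.null(domain_um))
    stop("`domain_um` is required when the network carries none",
         call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  sp <- spacing / supersample
  d <- as.integer(round(domain_um / sp))
  segs <- lapply(network$strands, function(st) {
    n <- nrow(st$points)
    if (n < 2L) return(NULL)
    list(p0 = st$points[-n, , drop = FALSE],
         p1 = st$points[-1, , drop = FALSE],
         r0 = st$radii_um[-n], r1 = st$radii_um[-1])
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs))
    return(voxel_grid(array(0, d), sp))
  p0 <- do.call(rbind, lapply(segs, `[[`, "p0"))
  p1 <- do.call(rbind, lapply(segs, `[[`, "p1"))
  r0 <- unlist(lapply(segs, `[[`, "r0"))
  r1 <- unlist(lapply(segs, `[[`, "r1"))
  mask <- cpp_stamp_capsules(p0, p1, r0, r1, d, sp)
  voxel_grid(array(as.numeric(mask), d), sp)
}

# separable Gaussian low-pass via the analytic spectrum (circular boundary)
gaussian_blur_fft <- function(values, spacing, std_um) {
  if (all(std_um <= 0)) return(values)
  d <- dim(values)
  kz <- fft_wavenumbers(d[1], spacing[1])
  ky <- fft_wavenumbers(d[2], spacing[2])
  kx <- fft_wavenumbers(d[3], spacing[3])
  q <- outer(outer(std_um[1]^2 * kz^2, std_um[2]^2 * ky^2, "+"),
             std_um[3]^2 * kx^2, "+")
  Re(stats::fft(stats::fft(values) * exp(-q / 2), inverse = TRUE)) / prod(d)
}

#' Simulate a two-photon image from a binary render
#'
#' The high-resolution binary volume is blurred with the Gaussian PSF
#' model, block-averaged down to the target resolution (detector
#' integration), linearly mapped so that background occupancy reads `I_B`
#' and full occupancy `I_F`, and corrupted by the Poisson surrogate: a
#' seeded Gaussian variate per voxel with variance equal to the noise-free
#' intensity. Negative intensities are clamped to zero.
#'
#' @param binary binary [voxel_grid()] from [render_binary()] at
#'   `config$spacing_um / config$supersample` resolution.
#' @param config a [sim_config()].
#' @param noise set `FALSE` for the noise-free intensity image.
#' @return A [voxel_grid()] at the target resolution with attribute `cnr`.
#' @export
simulate_image <- function(binary, config, noise = TRUE) {
  stopifnot_voxel_grid(binary)
  blurred <- gaussian_blur_fft(binary$values, binary$spacing,
                               config$psf_std_um)
  k <- rep(config$supersample, 3L)
  if (config$supersample > 1L) {
    d <- dim(blurred)
    if (any(d %% k != 0))
      stop("binary grid is not a multiple of the supersampling factor",
           call. = FALSE)
    blurred <- block_downsample(blurred, k)
  }
  intensity <- config$I_B + (config$I_F - config$I_B) *
    pmin(pmax(blurred, 0), 1)
  if (noise) {
    seed_keep <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(seed_keep))
      assign(".Random.seed", seed_keep, .GlobalEnv), add = TRUE)
    set.seed(config$seed)
    intensity <- intensity +
      stats::rnorm(length(intensity), 0, sqrt(intensity))
    intensity[intensity < 0] <- 0
  }
  ## block averaging shifts voxel centres by half the removed fine voxels
  out <- voxel_grid(array(intensity, dim(blurred)), config$spacing_um,
                    binary$origin + (k - 1) / 2 * binary$spacing)
  attr(out, "cnr") <- config$cnr
  out
}
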