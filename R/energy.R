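## Multi-scale Laplacian-of-Gaussian matched filtering in the Fourier domain.
##
## The matched filter for a vessel of radius R is (variance-weighted
## Laplacian) o (Gaussian, std sigma) o (ideal kernel, radius r), with
## R^2 = sigma^2 + r^2. All three factors have analytic Fourier transforms,
## so each scale is a single spectral multiplication. Bright structure on a
## dark background yields negative filter response ("energy"); more negative
## means more centerline-like.

# angular wavenumbers (rad/um) for an axis of n samples at voxel length d
fft_wavenumbers <- function(n, d) {
  j <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2)):-1)[seq_len(n)]
  if (n == 1L) j <- 0
  2 * pi * j / (n * d)
}

# unit-mass solid-sphere and spherical-shell transforms of radius r at
# radial wavenumber k; both -> 1 as k*r -> 0
sphere_xform <- function(u) {
  out <- numeric(length(u))
  small <- u < 1e-4
  out[small] <- 1 - u[small]^2 / 10
  ub <- u[!small]
  out[!small] <- 3 * (sin(ub) - ub * cos(ub)) / ub^3
  out
}

shell_xform <- function(u) {
  out <- numeric(length(u))
  small <- u < 1e-4
  out[small] <- 1 - u[small]^2 / 6
  ub <- u[!small]
  out[!small] <- sin(ub) / ub
  out
}

# per-axis half support (um) of the matched filter at bank scale i;
# nsig Gaussian tail standard deviations
kernel_support_um <- function(bank, i, nsig = 3) {
  bank$scales$r_ideal[i] + nsig * scale_sigma_eff(bank, i)
}

#' Analytic spectrum of one matched-filter scale
#'
#' Samples the closed-form Fourier transform of the matched filter on the
#' discrete spectral grid of a target volume. The spectrum is the product of
#' three real factors: a variance-weighted Laplacian `-(sum_a
#' sigma_eff[a]^2 k_a^2)` (each second derivative weighted by the Gaussian
#' variance on that axis so responses are comparable across scales and
#' anisotropic blurring), an anisotropic Gaussian `exp(-sum_a sigma_eff[a]^2
#' k_a^2 / 2)`, and a unit-mass ideal kernel `f_S * S(kr) + (1 - f_S) *
#' A(kr)` mixing the solid-sphere transform `S` and spherical-shell transform
#' `A` (both 1 at `k = 0`). The spectrum is zero at the origin, so constant
#' images filter to zero.
#'
#' @param bank a [scale_bank()].
#' @param index scale row in the bank.
#' @param dim integer length-3 target grid dimensions `(z, y, x)`.
#' @param spacing voxel lengths (um), length 3.
#' @return Real 3-D array of the sampled spectrum (DC bin first, FFT layout).
#' @export
kernel_spectrum <- function(bank, index, dim, spacing) {
  s <- bank$scales[index, ]
  sig <- scale_sigma_eff(bank, index)
  sup <- kernel_support_um(bank, index, nsig = 2)
  ext <- dim * spacing
  if (any(sup > ext / 2))
    stop(sprintf(
      "scale R = %.3g um exceeds grid support (half-extent %s um)",
      s$R, paste(format(ext / 2, digits = 3), collapse = " x ")),
      call. = FALSE)
  kz <- fft_wavenumbers(dim[1], spacing[1])
  ky <- fft_wavenumbers(dim[2], spacing[2])
  kx <- fft_wavenumbers(dim[3], spacing[3])
  ## sum_a sigma_eff[a]^2 k_a^2 over the 3-D grid
  q <- outer(outer(sig[1]^2 * kz^2, sig[2]^2 * ky^2, "+"), sig[3]^2 * kx^2, "+")
  spec <- -q * exp(-q / 2)
  if (s$r_ideal > 0) {
    k2 <- outer(outer(kz^2, ky^2, "+"), kx^2, "+")
    u <- sqrt(k2) * s$r_ideal
    ideal <- bank$f_S * sphere_xform(u) + (1 - bank$f_S) * shell_xform(u)
    spec <- spec * array(ideal, dim)
  }
  spec
}

#' Filter a volume with every scale of the bank
#'
#' Convolves the image with each matched filter by spectral multiplication
#' (circular boundary). The filtering is linear, so superposition holds
#' exactly: the response to a weighted sum of images is the weighted sum of
#' responses.
#'
#' @param image a [voxel_grid()].
#' @param bank a [scale_bank()].
#' @return Object of class `energy_stack`: list of per-scale 3-D energy
#'   arrays (same shape as the input) with the bank attached as an attribute.
#' @seealso [project_scales()] to collapse the stack to energy/size fields.
#' @export
filter_multiscale <- function(image, bank) {
  stopifnot_voxel_grid(image)
  d <- dim(image$values)
  F_img <- stats::fft(image$values)
  n <- prod(d)
  out <- vector("list", nrow(bank$scales))
  for (i in seq_along(out)) {
    spec <- kernel_spectrum(bank, i, d, image$spacing)
    out[[i]] <- Re(stats::fft(F_img * spec, inverse = TRUE)) / n
  }
  structure(out, class = "energy_stack", bank = bank,
            spacing = image$spacing, origin = image$origin)
}

#' Project a multi-scale energy stack to energy and size fields
#'
#' Collapses the 4-D (scale by space) response to two 3-D fields. Per voxel,
#' only scales with negative response participate; if none is negative the
#' voxel gets energy 0 and size 0. The shell-matched ("annular") size
#' estimate is the radius of the least-energy scale; the sphere-matched
#' estimate is the energy-magnitude-weighted mean radius over all negative
#' scales; the combined estimate mixes the two by the bank's spherical
#' fraction `f_S`. The reported energy is the stack value at the bank scale
#' nearest the combined estimate in log-radius (ties toward the smaller
#' scale).
#'
#' @param stack an `energy_stack` from [filter_multiscale()].
#' @param bank the [scale_bank()] used to build the stack; defaults to the
#'   bank attached to `stack`.
#' @return Object of class `energy_fields`: list with `energy` and `size`
#'   [voxel_grid()]s (size in um; energy <= 0 everywhere) and the bank.
#' @export
project_scales <- function(stack, bank = attr(stack, "bank")) {
  R <- bank$scales$R
  nS <- length(R)
  d <- dim(stack[[1]])
  n <- prod(d)
  min_e <- stack[[1]]
  min_R <- array(R[1], d)
  wsum <- numeric(n)
  wRsum <- numeric(n)
  e1 <- as.numeric(stack[[1]])
  neg <- e1 < 0
  wsum[neg] <- -e1[neg]
  wRsum[neg] <- -e1[neg] * R[1]
  if (nS > 1) for (i in 2:nS) {
    ei <- as.numeric(stack[[i]])
    upd <- ei < min_e
    min_R[upd] <- R[i]
    min_e[upd] <- ei[upd]
    neg <- ei < 0
    wsum[neg] <- wsum[neg] - ei[neg]
    wRsum[neg] <- wRsum[neg] - ei[neg] * R[i]
  }
  any_neg <- wsum > 0
  size <- numeric(n)
  energy <- numeric(n)
  if (any(any_neg)) {
    ann <- as.numeric(min_R)[any_neg]
    sph <- wRsum[any_neg] / wsum[any_neg]
    comb <- bank$f_S * sph + (1 - bank$f_S) * ann
    size[any_neg] <- comb
    ## nearest bank scale in log-R, ties toward the smaller scale
    if (nS > 1) {
      mids <- (log(R[-nS]) + log(R[-1])) / 2
      idx <- findInterval(log(comb), mids, left.open = TRUE) + 1L
    } else idx <- rep(1L, length(comb))
    which_neg <- which(any_neg)
    for (s in unique(idx)) {
      sel <- which_neg[idx == s]
      energy[sel] <- stack[[s]][sel]
    }
    ## a voxel negative somewhere may be non-negative at the looked-up
    ## scale; energy is clamped to <= 0 by construction of the report
    energy[energy > 0] <- 0
  }
  spacing <- attr(stack, "spacing")
  origin <- attr(stack, "origin")
  structure(list(
    energy = voxel_grid(array(energy, d), spacing, origin),
    size = voxel_grid(array(size, d), spacing, origin),
    bank = bank), class = "energy_fields")
}

#' @export
print.energy_fields <- function(x, ...) {
  cat("<energy_fields>\n  energy: ")
  print(x$energy)
  cat("  size:   ")
  print(x$size)
  invisible(x)
}

#' One-call energy and size fields
#'
#' Convenience wrapper: [filter_multiscale()] followed by
#' [project_scales()].
#'
#' @inheritParams filter_multiscale
#' @return An `energy_fields` object.
#' @export
energy_fields <- function(image, bank) {
  project_scales(filter_multiscale(image, bank), bank)
}
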