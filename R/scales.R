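#' Plan the matched-filter scale sampling
#'
#' Scale space is sampled geometrically in matched-vessel radius `R`. One
#' octave is a doubling of the matched filter (vessel) volume, i.e. a radius
#' factor of `2^(1/3)`; the bank samples `scales_per_octave` radii per volume
#' doubling so consecutive filter volumes differ by `2^(1/scales_per_octave)`.
#' The sequence is anchored at `r_min` and spans `ceiling(3 * log2(r_max /
#' r_min))` octaves, so the last sample may slightly over- or undershoot
#' `r_max`.
#'
#' @param r_min,r_max smallest and largest matched vessel radius (um).
#' @param scales_per_octave positive integer sampling density per volume
#'   doubling.
#' @return Numeric vector of matched radii `R` (um), strictly increasing;
#'   `r_min * 2^(i / (3 * scales_per_octave))` for `i = 0, ..., N - 1` with
#'   `N = ceiling(3 * log2(r_max / r_min)) * scales_per_octave` (at least 1).
#' @examples
#' length(plan_scales(1.5, 60, 6)) # 96 scales over 16 volume octaves
#' @export
plan_scales <- function(r_min, r_max, scales_per_octave = 3L) {
  if (!is.finite(r_min) || !is.finite(r_max) || r_min <= 0 || r_max <= 0)
    stop("radii must be positive and finite", call. = FALSE)
  if (r_min > r_max) stop("`r_min` must not exceed `r_max`", call. = FALSE)
  if (scales_per_octave < 1) stop("`scales_per_octave` must be >= 1", call. = FALSE)
  spo <- as.integer(scales_per_octave)
  n <- max(1L, as.integer(ceiling(3 * log2(r_max / r_min)) * spo))
  r_min * 2^((seq_len(n) - 1) / (3 * spo))
}

#' Split a matched radius into Gaussian and ideal-kernel parts
#'
#' The matched filter at radius `R` is the convolution of a Gaussian of
#' standard deviation `sigma` with an ideal (sphere/shell) kernel of radius
#' `r`, and `R^2 = sigma^2 + r^2`. The Gaussian fraction
#' `f_G = sigma / (sigma + r)` sets the trade-off between noise robustness
#' (large `f_G`) and size/position accuracy (small `f_G`).
#'
#' @param R matched vessel radius (um), positive.
#' @param f_G Gaussian fraction in `[0, 1]`.
#' @return List with `sigma` and `r_ideal` (um) satisfying both defining
#'   relations; `f_G = 1` gives `(R, 0)` (pure Gaussian), `f_G = 0` gives
#'   `(0, R)` (pure ideal kernel).
#' @examples
#' split_radius(sqrt(2), 0.5) # sigma = r = 1
#' @export
split_radius <- function(R, f_G) {
  if (!is.finite(R) || R <= 0) stop("`R` must be positive", call. = FALSE)
  if (!is.finite(f_G) || f_G < 0 || f_G > 1)
    stop("`f_G` must lie in [0, 1]", call. = FALSE)
  if (f_G >= 1) return(list(sigma = R, r_ideal = 0))
  t <- f_G / (1 - f_G)
  r_ideal <- R / sqrt(1 + t^2)
  list(sigma = t * r_ideal, r_ideal = r_ideal)
}

#' Build a matched-filter scale bank
#'
#' @param r_min,r_max radius range (um) passed to [plan_scales()].
#' @param scales_per_octave sampling density per volume doubling.
#' @param f_G Gaussian fraction in `[0, 1]` (see [split_radius()]).
#' @param f_S spherical fraction in `[0, 1]` of the ideal kernel: 1 matches a
#'   lumen-filling (plasma-label) signal, 0 a vessel-wall (endothelial-label)
#'   shell.
#' @param psf_std_um per-axis Gaussian standard deviation (um) of the
#'   microscope point-spread-function model, combined with each scale's
#'   Gaussian by variance addition. Default no PSF.
#' @return Object of class `scale_bank`: a list with `scales` (data frame of
#'   `R`, `sigma`, `r_ideal` and per-axis `sigma_eff_*`), `f_G`, `f_S`,
#'   `scales_per_octave`, `psf_std_um`.
#' @export
scale_bank <- function(r_min, r_max, scales_per_octave = 3L,
                       f_G = 0.5, f_S = 1, psf_std_um = c(0, 0, 0)) {
  if (!is.finite(f_S) || f_S < 0 || f_S > 1)
    stop("`f_S` must lie in [0, 1]", call. = FALSE)
  if (length(psf_std_um) == 1L) psf_std_um <- rep(psf_std_um, 3L)
  if (length(psf_std_um) != 3L || any(psf_std_um < 0))
    stop("`psf_std_um` must be 3 non-negative stds (um)", call. = FALSE)
  R <- plan_scales(r_min, r_max, scales_per_octave)
  parts <- lapply(R, split_radius, f_G = f_G)
  sigma <- vapply(parts, `[[`, numeric(1), "sigma")
  r_ideal <- vapply(parts, `[[`, numeric(1), "r_ideal")
  eff <- sqrt(outer(sigma^2, psf_std_um^2, "+")) # n x 3, variance addition
  scales <- data.frame(index = seq_along(R), R = R, sigma = sigma,
                       r_ideal = r_ideal,
                       sigma_eff_z = eff[, 1], sigma_eff_y = eff[, 2],
                       sigma_eff_x = eff[, 3])
  structure(list(scales = scales, f_G = f_G, f_S = f_S,
                 scales_per_octave = as.integer(scales_per_octave),
                 psf_std_um = as.numeric(psf_std_um)),
            class = "scale_bank")
}

#' @export
print.scale_bank <- function(x, ...) {
  s <- x$scales
  cat(sprintf(
    "<scale_bank> %d scales, R = %.3g..%.3g um, %d/octave, f_G = %g, f_S = %g\n",
    nrow(s), min(s$R), max(s$R), x$scales_per_octave, x$f_G, x$f_S))
  invisible(x)
}

# per-axis effective sigma (um) for scale row i, as a length-3 vector
scale_sigma_eff <- function(bank, i) {
  as.numeric(bank$scales[i, c("sigma_eff_z", "sigma_eff_y", "sigma_eff_x")])
}
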