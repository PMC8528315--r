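# closed-form spatial kernel for the isotropic, PSF-free matched filter:
# sigma^2 * Laplacian of (unit-mass Gaussian (*) unit-mass ball of radius r),
# evaluated radially via the erf expression for Gaussian-ball convolution
# and high-precision numerical radial derivatives
spatial_kernel_oracle <- function(rho, sigma, r) {
  F <- function(p) {
    0.5 * (erf_((r - p) / (sqrt(2) * sigma)) +
             erf_((r + p) / (sqrt(2) * sigma))) -
      (sigma / (p * sqrt(2 * pi))) *
      (exp(-(r - p)^2 / (2 * sigma^2)) - exp(-(r + p)^2 / (2 * sigma^2)))
  }
  h <- 1e-3
  p <- pmax(rho, 2 * h) # keep the removable rho = 0 singularity away
  lap <- (F(p + h) - 2 * F(p) + F(p - h)) / h^2 +
    (2 / p) * (F(p + h) - F(p - h)) / (2 * h)
  sigma^2 * lap / (4 / 3 * pi * r^3)
}
erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

test_that("analytic spectrum matches the closed-form spatial kernel", {
  n <- 32
  bank <- scale_bank(4, 4, 1, f_G = 0.5, f_S = 1)
  spec <- kernel_spectrum(bank, 1, c(n, n, n), c(1, 1, 1))
  ## DC bin: the Laplacian annihilates constants
  expect_identical(spec[1, 1, 1], 0)
  kern <- Re(fft(spec, inverse = TRUE)) / n^3
  ## circular distance from the kernel origin at voxel (1,1,1)
  dlt <- pmin(0:(n - 1), n - (0:(n - 1)))
  rho <- sqrt(outer(outer(dlt^2, dlt^2, "+"), dlt^2, "+"))
  s <- split_radius(4, 0.5)
  oracle <- array(spatial_kernel_oracle(rho, s$sigma, s$r_ideal), dim(rho))
  rel <- sqrt(sum((kern - oracle)^2) / sum(oracle^2))
  expect_lt(rel, 1e-3)
  ## bright centre => negative kernel peak
  expect_lt(kern[1, 1, 1], 0)
})

test_that("FFT filtering equals direct circular convolution", {
  n <- 16
  set.seed(42)
  img <- voxel_grid(array(rnorm(n^3)^2, c(n, n, n)))
  bank <- scale_bank(3, 3, 1, f_G = 0.5, f_S = 1)
  out <- filter_multiscale(img, bank)[[1]]
  kern <- Re(fft(kernel_spectrum(bank, 1, c(n, n, n), c(1, 1, 1)),
                 inverse = TRUE)) / n^3
  ## direct sum over all circularly shifted kernel taps
  acc <- array(0, c(n, n, n))
  for (dz in 0:(n - 1)) for (dy in 0:(n - 1)) for (dx in 0:(n - 1)) {
    w <- kern[dz + 1, dy + 1, dx + 1]
    if (abs(w) < 1e-12) next
    iz <- ((seq_len(n) - 1 - dz) %% n) + 1
    iy <- ((seq_len(n) - 1 - dy) %% n) + 1
    ix <- ((seq_len(n) - 1 - dx) %% n) + 1
    acc <- acc + w * img$values[iz, iy, ix]
  }
  expect_lt(sqrt(sum((out - acc)^2) / sum(acc^2)), 1e-3)
})

test_that("filtering is exactly linear and annihilates constants", {
  n <- 16
  set.seed(7)
  bank <- scale_bank(2, 4, 2, f_G = 0.6, f_S = 0.7)
  i1 <- array(rnorm(n^3), c(n, n, n))
  i2 <- array(rnorm(n^3), c(n, n, n))
  f1 <- filter_multiscale(voxel_grid(i1), bank)
  f2 <- filter_multiscale(voxel_grid(i2), bank)
  fs <- filter_multiscale(voxel_grid(2.5 * i1 - 1.25 * i2), bank)
  for (k in seq_along(fs)) {
    comb <- 2.5 * f1[[k]] - 1.25 * f2[[k]]
    expect_lt(max(abs(fs[[k]] - comb)) / max(abs(comb)), 1e-10)
  }
  const <- filter_multiscale(voxel_grid(array(3.7, c(n, n, n))), bank)
  for (k in seq_along(const))
    expect_lt(max(abs(const[[k]])), 1e-10)
})

test_that("oversized scales raise a scale-too-large error", {
  bank <- scale_bank(20, 20, 1, f_G = 0.5)
  expect_error(kernel_spectrum(bank, 1, c(16, 16, 16), c(1, 1, 1)),
               "exceeds grid support")
  img <- voxel_grid(array(0, c(16, 16, 16)))
  expect_error(filter_multiscale(img, bank), "exceeds grid support")
})

stack_stub <- function(energies, spacing = c(1, 1, 1)) {
  structure(lapply(energies, function(e) array(e, c(1, 1, 1))),
            class = "energy_stack", spacing = spacing, origin = c(0, 0, 0))
}

test_that("scale projection follows the annular/spherical mixing rules", {
  ## spherical signal: |energy|-weighted mean radius, energy sampled at the
  ## nearest bank scale in log-radius
  bank <- bank_stub(c(2, 4, 8), f_S = 1)
  pr <- project_scales(stack_stub(c(-1, -3, -1)), bank)
  expect_equal(pr$size$values[1, 1, 1], (2 * 1 + 4 * 3 + 8 * 1) / 5)
  expect_equal(pr$size$values[1, 1, 1], 4.4)
  expect_equal(pr$energy$values[1, 1, 1], -3)

  ## annular signal, single negative scale: plain argmin
  bank0 <- bank_stub(c(2, 4, 8), f_S = 0)
  pr <- project_scales(stack_stub(c(0.5, -3, 0.2)), bank0)
  expect_equal(pr$size$values[1, 1, 1], 4)
  expect_equal(pr$energy$values[1, 1, 1], -3)

  ## non-negative everywhere: ignored voxel
  pr <- project_scales(stack_stub(c(0.1, 0, 0.3)), bank)
  expect_equal(pr$size$values[1, 1, 1], 0)
  expect_equal(pr$energy$values[1, 1, 1], 0)
})

test_that("projected energy is never positive and size accompanies energy", {
  set.seed(11)
  img <- voxel_grid(array(rnorm(16^3)^2, c(16, 16, 16)))
  fl <- energy_fields(img, scale_bank(2, 4, 2, f_G = 0.6, f_S = 0.5))
  expect_true(all(fl$energy$values <= 0))
  expect_true(all(fl$size$values[fl$energy$values < 0] > 0))
  expect_true(all(is.finite(fl$energy$values)))
})

test_that("sphere response minimum sits at the centre, at the scale the
           continuous theory predicts", {
  a <- 5
  img <- sphere_image(48, a)
  bank <- scale_bank(2, 8, 3, f_G = 0.5, f_S = 1)
  stk <- filter_multiscale(img, bank)
  mins <- vapply(stk, min, numeric(1))
  best <- which.min(mins)
  expect_equal(as.integer(arrayInd(which.min(stk[[best]]),
                                   dim(img$values))),
               c(24L, 24L, 24L), tolerance = 1) # centre voxel (24/25)
  ## independent radial-quadrature oracle for the argmin scale
  Rf <- exp(seq(log(2), log(9), length.out = 120))
  resp <- vapply(Rf, oracle_sphere_response, numeric(1), a = a, f_G = 0.5)
  R_oracle <- Rf[which.min(resp)]
  step <- 2^(1 / 9)
  expect_lt(abs(log(bank$scales$R[best] / R_oracle)), log(step) * 1.01)
})

test_that("sphere radii in the bank interior are recovered within one
           scale step by the size field", {
  bank <- scale_bank(1.5, 12, 3, f_G = 0.5, f_S = 1)
  step <- 2^(1 / 9)
  for (a in c(3, 3.5, 4)) {
    img <- sphere_image(64, a)
    fl <- energy_fields(img, bank)
    ctr <- which.min(fl$energy$values)
    est <- fl$size$values[ctr]
    expect_lt(abs(log(est / a)), log(step),
              label = sprintf("size %.2f for radius %g", est, a))
  }
})
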