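grid_of <- function(d, spacing = c(1, 1, 1))
  voxel_grid(array(0, d), spacing)

test_that("volume rendering matches analytic ball volumes; centerline
           rendering marks exactly the trace voxels", {
  g <- grid_of(c(24, 24, 24))
  v <- data.frame(id = 1L, z = 12L, y = 12L, x = 12L, z_um = 11,
                  y_um = 11, x_um = 11, radius_um = 5, energy = -1)
  m <- render_mask(v, g, fill = "volume")
  ball <- 4 / 3 * pi * 125
  expect_lt(abs(sum(m$values) - ball) / ball, 0.05)

  ed <- list(toy_edge(1, 2, -3, n = 5L))
  mc <- render_mask(ed, g, fill = "centerline", radius_scale = 0)
  idx <- ed[[1]]$trace
  expect_equal(sum(mc$values), nrow(idx))
  expect_true(all(mc$values[idx] == 1))

  expect_equal(sum(render_mask(list(), g)$values), 0)
})

test_that("threshold sweeps agree with exhaustive confusion tables on
           disjoint objects", {
  g <- grid_of(c(16, 16, 48))
  truth <- grid_of(c(16, 16, 48))
  ## three disjoint true balls; a fourth object is pure false positive
  centers <- rbind(c(8, 8, 8), c(8, 8, 24), c(8, 8, 40), c(2, 2, 2))
  radii <- c(3, 3, 3, 2)
  for (i in 1:3)
    truth$values <- pmax(truth$values,
                         render_mask(data.frame(id = i, z = 0, y = 0, x = 0,
                                                z_um = centers[i, 1],
                                                y_um = centers[i, 2],
                                                x_um = centers[i, 3],
                                                radius_um = radii[i],
                                                energy = -1),
                                     g)$values)
  objs <- data.frame(id = 1:4, z = 0, y = 0, x = 0,
                     z_um = centers[, 1], y_um = centers[, 2],
                     x_um = centers[, 3], radius_um = radii,
                     energy = c(-9, -7, -5, -2))
  sw <- threshold_sweep(objs, truth, g)
  ## brute force: render each prefix of the energy-sorted objects
  n_tot <- prod(dim(truth$values))
  for (k in 0:4) {
    keep <- objs[objs$energy <= c(-Inf, sort(objs$energy))[k + 1], ,
                 drop = FALSE]
    m <- if (nrow(keep)) render_mask(keep, g)$values else truth$values * 0
    TP <- sum(m == 1 & truth$values == 1)
    FP <- sum(m == 1 & truth$values == 0)
    row <- sw$roc[k + 1, ]
    expect_equal(c(row$TP, row$FP), c(TP, FP))
    expect_equal(row$TN + row$FN, n_tot - TP - FP)
  }
  ## strictest threshold = empty mask = background-fraction accuracy
  expect_equal(sw$roc$accuracy[1], mean(truth$values == 0))
  ## best operating point keeps the three true balls, drops the impostor
  expect_equal(sum(sw$keep_best), 3)
  ## ROC validity: sensitivity and false-positive rate non-decreasing as
  ## the threshold loosens
  expect_true(all(diff(sw$roc$sensitivity) >= -1e-12))
  expect_true(all(diff(1 - sw$roc$specificity) >= -1e-12))
})

test_that("the intensity benchmark is perfect on a noise-free two-level
           image", {
  g <- grid_of(c(12, 12, 12))
  truth <- g
  truth$values[4:8, 4:8, 4:8] <- 1
  img <- g
  img$values <- 25 + 75 * truth$values
  sw <- intensity_sweep(img, truth)
  expect_equal(sw$best$accuracy, 1)
  expect_true(sw$best$threshold > 25 && sw$best$threshold <= 100)
  ## trivial classifiers bound the best accuracy from below
  expect_gte(sw$best$accuracy, max(mean(truth$values), 1 - mean(truth$values)))
})

test_that("percent errors are signed, zero at equality, and antisymmetric
           up to the denominator", {
  bs <- function(l, a, v, b) bulk_stats_from_totals(l, a, v, b, 1)
  truth <- bs(100, 10, 1, 50)
  expect_equal(unname(stat_percent_errors(truth, truth)), rep(0, 4))
  up <- bs(110, 10, 1, 50)
  expect_equal(stat_percent_errors(up, truth)[["length"]], 10)
  set.seed(8)
  for (i in 1:5) {
    m <- bs(runif(1, 50, 150), runif(1, 5, 15), runif(1, 0.5, 2),
            runif(1, 10, 90))
    fwd <- stat_percent_errors(m, truth)
    rev <- stat_percent_errors(truth, m)
    ## e_rev = -e_fwd / (1 + e_fwd/100), numerically
    expect_equal(unname(rev), unname(-fwd / (1 + fwd / 100)),
                 tolerance = 1e-9)
  }
  bad <- bs(0, 10, 1, 5)
  expect_error(stat_percent_errors(truth, bad), "positive")
})

test_that("the automated pipeline nails a clean high-contrast tube and
           reports reproducibly", {
  net <- tube_network(radius = 3, x0 = 10, x1 = 86, zy = 14,
                      domain = c(28, 28, 96))
  bin <- render_binary(net, spacing = 1, supersample = 2)
  cfg <- sim_config(I_F = 200, I_B = 25, psf_std_um = c(1, 0.5, 0.5),
                    supersample = 2, seed = 31)
  img <- simulate_image(bin, cfg, noise = FALSE)
  truth <- render_binary(net, spacing = 1, supersample = 1)
  ts <- bulk_stats(to_cylinders(net), 1, prod(c(28, 28, 96)) / 1e9)
  params <- list(r_min = 2, r_max = 6, scales_per_octave = 3, f_G = 0.6,
                 f_S = 1, psf_std_um = c(1, 0.5, 0.5))
  rep1 <- run_automated_pipeline(img, params, truth, ts)
  expect_lte(abs(rep1$percent_errors[["volume"]]), 60) # radius bias squared
  expect_gt(rep1$best_edge_accuracy, 0.97)
  expect_gte(rep1$best_edge_accuracy,
             max(mean(truth$values), 1 - mean(truth$values)))
  ## reproducibility of the full report under identical inputs
  rep2 <- run_automated_pipeline(img, params, truth, ts)
  expect_identical(rep1$edge_sweep$roc, rep2$edge_sweep$roc)
  expect_identical(rep1$measured_stats, rep2$measured_stats)
})
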