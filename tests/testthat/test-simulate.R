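test_that("offset grids have the expected point counts and exact endpoints", {
  g <- make_offset_grid(-5, 5, 0.2)
  expect_length(g, 51)
  expect_identical(g$offsets[c(1, 51)], c(-5, 5))
  expect_true(any(g$offsets == 0))

  g2 <- make_offset_grid(-5, 5, 0.1)
  expect_length(g2, 101)
  expect_equal(max(abs(diff(g2$offsets) - 0.1)), 0, tolerance = 1e-12)

  expect_error(make_offset_grid(0, 0, 0.1), "greater")
  expect_error(make_offset_grid(-5, 5, -0.1), "positive")
  expect_error(make_offset_grid(-5, 5, 0.3), "integer multiple")
})

test_that("Lorentzian pools satisfy peak and FWHM definitions", {
  g <- make_offset_grid(-5, 5, 0.1)
  p <- pool_spec(0.4, 1.5, 2.0)
  v <- lorentzian_pool(g, p)
  expect_equal(v[g$offsets == 1.5], 0.4)
  expect_equal(v[g$offsets == 1.5 + 1], 0.2)  # center + fwhm/2
  expect_equal(v[g$offsets == 1.5 - 1], 0.2)
  expect_true(all(v >= 0 & v <= 0.4))
  expect_equal(lorentzian_pool(g, pool_spec(0, 0, 1)), numeric(101))
})

test_that("simulated Z-spectra follow the 1 - sum-of-pools model", {
  g <- make_offset_grid(-5, 5, 0.1)
  expect_equal(simulate_zspectrum(g, list())$values, rep(1, 101))

  water <- list(pool_spec(0.8, 0, 1.4))
  sp <- simulate_zspectrum(g, water)
  expect_equal(which.min(sp$values), 51L)  # minimum at 0 ppm
  expect_equal(sp$values, rev(sp$values))  # symmetric about water

  sp_all <- simulate_zspectrum(g, default_pools())
  amp <- sum(vapply(default_pools(), `[[`, numeric(1), "amplitude"))
  expect_true(all(sp_all$values >= 1 - amp & sp_all$values <= 1))

  too_much <- list(pool_spec(0.7, 0, 1), pool_spec(0.4, 3.5, 1))
  expect_error(simulate_zspectrum(g, too_much), "exceed")
})

test_that("simulation noise has the requested level and is seed-reproducible", {
  g <- make_offset_grid(-5, 5, 0.2)
  a <- simulate_zspectrum(g, noise_sd = 0.01, seed = 7)
  b <- simulate_zspectrum(g, noise_sd = 0.01, seed = 7)
  expect_identical(a$values, b$values)

  # empirical sd of the generated noise across many draws at interior offsets
  clean <- simulate_zspectrum(g)$values
  draws <- vapply(1:200, function(i) {
    simulate_zspectrum(g, noise_sd = 0.01, seed = 1000 + i)$values - clean
  }, numeric(51))
  keep <- clean > 0.2 & clean < 0.99  # away from the clipping bounds
  expect_gt(sum(keep) * 200, 5000)
  expect_equal(sd(draws[keep, ]), 0.01, tolerance = 0.1)
})

test_that("phantoms honour uniform fields, B0 maps and mask geometry", {
  g <- make_offset_grid(-5, 5, 0.2)
  vols <- simulate_phantom(2, 2, c(8, 8), grid = g, mask = "rect", seed = 1)
  expect_length(vols, 2)
  expect_equal(dim(vols[[1]]$data), c(8, 8, 2, 51))

  # uniform fields, no noise: every pixel equals the generating spectrum
  ref <- simulate_zspectrum(g, default_pools())$values
  expect_equal(vols[[1]]$data[3, 5, 1, ], ref)
  expect_equal(vols[[1]]$data[8, 8, 2, ], ref)
  expect_equal(slice_average(vols[[1]], 1)$values, ref)

  # per-pixel argmin at 0 ppm when the B0 field is zero
  mins <- apply(matrix(vols[[1]]$data[, , 1, ], ncol = 51), 1, which.min)
  expect_true(all(g$offsets[mins] == 0))

  # per-pixel B0 field shifts the water minimum pixel by pixel
  b0 <- matrix(0, 8, 8); b0[2, 2] <- 0.4
  vshift <- simulate_phantom(1, 1, c(8, 8), b0_field = b0, grid = g,
                             mask = "rect")[[1]]
  expect_equal(g$offsets[which.min(vshift$data[2, 2, 1, ])], 0.4)
  expect_equal(g$offsets[which.min(vshift$data[5, 5, 1, ])], 0)

  expect_error(simulate_phantom(1, 1, c(8, 8), b0_field = matrix(0, 4, 4)),
               "shape")
  expect_lt(sum(simulate_phantom(1, 1, c(8, 8), mask = "ellipse")[[1]]$mask), 64)
})

test_that("Gaussian augmentation multiplies rows and preserves the signal", {
  spectra <- synthetic_zspectra(30, grid101(), seed = 5)
  aug <- augment_gaussian(spectra, n_copies = 100, seed = 11)
  expect_equal(nrow(aug), 3000)

  noiseless <- augment_gaussian(spectra, n_copies = 3, noise_sd = 0, seed = 1)
  expect_equal(zs_values(noiseless)[1:3, ],
               zs_values(spectra)[c(1, 1, 1), ])

  # CLT: the mean of 100 noisy copies stays within 3 * 0.01/sqrt(100) of base
  one <- zspectra(zs_values(spectra)[1, , drop = FALSE], grid101())
  copies <- augment_gaussian(one, n_copies = 100, seed = 1)
  dev <- abs(colMeans(zs_values(copies)) - zs_values(one)[1, ])
  expect_true(all(dev <= 3 * 0.01 / sqrt(100)))

  expect_error(augment_gaussian(zspectra(matrix(numeric(0), 0, 101), grid101()), 2),
               "empty")
  expect_error(augment_gaussian(spectra, 0), "at least 1")
})

test_that("pixel-subsample augmentation yields slices-times-sizes spectra", {
  g <- make_offset_grid(-5, 5, 0.2)
  vol <- simulate_phantom(1, 2, c(10, 10), grid = g, mask = "rect",
                          noise_sd = 0.02, seed = 3)[[1]]
  sizes <- c(20, 50, 100)  # the full scheme uses seq(800, 1550, 50): 16 sizes
  expect_length(seq(800, 1550, by = 50), 16)

  aug <- augment_subsample(vol, sizes, seed = 9)
  expect_equal(nrow(aug), 2 * 3)
  expect_identical(zs_values(augment_subsample(vol, sizes, seed = 9)),
                   zs_values(aug))

  # a subsample of every pixel is exactly the slice average
  full <- augment_subsample(vol, sizes = 100, seed = 1)
  expect_equal(zs_values(full)[1, ], slice_average(vol, 1)$values)
  expect_equal(zs_values(full)[2, ], slice_average(vol, 2)$values)

  expect_error(augment_subsample(vol, sizes = 101), "exceeds")
})
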