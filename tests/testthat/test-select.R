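test_that("spline reconstruction honours its interpolation contract", {
  g <- grid101()
  sp <- simulate_zspectrum(g)

  # full subset: identity
  full <- offset_subset(1:101, g)
  expect_equal(spline_reconstruct(full, sp$values, g), sp$values)
  expect_equal(subset_fitness(full, sp), 0)

  # exact at every selected offset
  sub <- offset_subset(c(3, 11, 26, 51, 70, 88, 99), g)
  recon <- spline_reconstruct(sub, sp$values[sub$indices], g)
  expect_equal(recon[sub$indices], sp$values[sub$indices])

  # a cubic polynomial is recovered exactly inside the subset hull
  x <- g$offsets
  cubic <- 0.5 + 0.01 * x - 0.002 * x^2 + 0.0015 * x^3
  sub4 <- offset_subset(c(1, 30, 70, 101), g)
  expect_equal(spline_reconstruct(sub4, cubic[sub4$indices], g), cubic,
               tolerance = 1e-12)

  # linear ramp with both endpoints: fitness 0
  ramp <- zspectrum(seq(0.1, 0.9, length.out = 101), g)
  sub_ends <- offset_subset(c(1, 25, 60, 101), g)
  expect_equal(subset_fitness(sub_ends, ramp), 0, tolerance = 1e-12)

  # constant extension beyond the extreme selected offsets
  inner <- offset_subset(c(20, 40, 60, 80), g)
  rec <- spline_reconstruct(inner, sp$values[inner$indices], g)
  expect_true(all(rec[1:19] == rec[20]))
  expect_true(all(rec[81:101] == rec[80]))

  expect_error(spline_reconstruct(offset_subset(c(1, 50, 101), g),
                                  sp$values[c(1, 50, 101)], g),
               "at least 4")
})

test_that("subset fitness matches an independent polynomial oracle on all C(9,4) subsets", {
  # on 4 support points the FMM cubic spline is the unique interpolating
  # cubic, so an explicit Vandermonde polynomial fit is an independent route
  g <- as_offset_grid(seq(-4, 4, 1))
  sp <- simulate_zspectrum(g, noise_sd = 0.02, seed = 21)
  combs <- combn(9, 4)
  oracle <- function(ix) {
    xs <- g$offsets[ix]
    cf <- solve(outer(xs, 0:3, `^`), sp$values[ix])
    xq <- pmin(pmax(g$offsets, min(xs)), max(xs))
    pred <- drop(outer(xq, 0:3, `^`) %*% cf)
    sqrt(mean((pred - sp$values)^2))
  }
  for (j in seq_len(ncol(combs))) {
    ix <- combs[, j]
    expect_equal(subset_fitness(offset_subset(ix, g), sp), oracle(ix),
                 tolerance = 1e-9)
  }
})

test_that("GA keeps subset cardinality and improves monotonically under elitism", {
  g <- grid101()
  sp <- simulate_zspectrum(g, noise_sd = 0.005, seed = 2)
  res <- ga_select(sp, p = 10, config = ga_config(max_generations = 60, seed = 1))
  expect_s3_class(res$best, "offset_subset")
  expect_length(res$best$indices, 10)  # round(10% x 101)
  expect_false(anyDuplicated(res$best$indices) > 0)
  expect_true(all(diff(res$best$indices) > 0))
  expect_true(all(diff(res$history) <= 1e-12))
  expect_equal(res$best$fitness, tail(res$history, 1))
  expect_true(res$termination_reason %in%
                c("target_reached", "stalled", "max_generations"))

  # determinism: identical config, identical result
  res2 <- ga_select(sp, p = 10, config = ga_config(max_generations = 60, seed = 1))
  expect_identical(res2$best$indices, res$best$indices)

  # target_loss short-circuits the search
  easy <- ga_select(sp, p = 30, config = ga_config(target_loss = 0.05, seed = 3))
  expect_equal(easy$termination_reason, "target_reached")

  expect_error(ga_select(sp, k = 3, config = ga_config(seed = 1)), "at least 4")
  expect_error(ga_select(sp, k = 200, config = ga_config(seed = 1)), "exceeds")
})

test_that("GA crossover and mutation preserve cardinality and range", {
  withr::with_seed(42, {
    for (rep in 1:50) {
      n <- sample(20:101, 1)
      k <- sample(4:min(15, n - 1), 1)
      a <- sort(sample.int(n, k))
      b <- sort(sample.int(n, k))
      child <- zspeed:::complete_subset(
        zspeed:::mutate_subset(zspeed:::crossover_subsets(a, b, k), n, 0.3),
        k, n)
      expect_length(child, k)
      expect_false(anyDuplicated(child) > 0)
      expect_true(all(child >= 1 & child <= n))
    }
  })
})

test_that("GA attains the exhaustive optimum on a small grid", {
  g <- as_offset_grid(seq(-5, 5, length.out = 12))
  sp <- simulate_zspectrum(g, noise_sd = 0.01, seed = 3)
  combs <- combn(12, 4)
  fits <- apply(combs, 2, function(ix) subset_fitness(offset_subset(ix, g), sp))
  opt <- min(fits)
  res <- ga_select(sp, k = 4,
                   config = ga_config(population_size = 40,
                                      max_generations = 200, seed = 5))
  expect_equal(res$best$fitness, opt, tolerance = 1e-12)
})

test_that("best-candidate selection ranks by own and cross-mean fitness", {
  g <- grid101()
  subs <- lapply(c(1, 2, 3), function(s) {
    su <- prng_select(g, 10, seed = s)
    su
  })
  subs[[1]]$fitness <- 0.012; subs[[2]]$fitness <- 0.009; subs[[3]]$fitness <- 0.015
  expect_identical(select_best_candidate(subs)$indices, subs[[2]]$indices)
  expect_identical(select_best_candidate(subs[2])$indices, subs[[2]]$indices)
  expect_error(select_best_candidate(list()), "empty")

  # cross-mean agrees with a direct mean-RMSE enumeration
  spectra <- withr::with_seed(99, lapply(1:3, function(i) {
    simulate_zspectrum(g, jittered_pools(), noise_sd = 0.01, seed = 30 + i)
  }))
  mean_fits <- vapply(subs, function(su) {
    mean(vapply(spectra, function(sp) subset_fitness(su, sp), numeric(1)))
  }, numeric(1))
  picked <- select_best_candidate(subs, spectra, mode = "cross-mean")
  expect_identical(picked$indices, subs[[which.min(mean_fits)]]$indices)
  expect_equal(picked$fitness, min(mean_fits))

  # own mode with explicit spectra requires one spectrum per candidate
  expect_error(select_best_candidate(subs, spectra[1:2], mode = "own"),
               "one spectrum per candidate")
})

test_that("PRNG and fixed-list selectors behave as documented", {
  g <- grid101()
  s <- prng_select(g, 10, seed = 8)
  expect_length(s$indices, 10)
  expect_false(anyDuplicated(s$indices) > 0)
  expect_identical(prng_select(g, 10, seed = 8)$indices, s$indices)
  expect_identical(prng_select(g, 101, seed = 1)$indices, 1:101)
  expect_error(prng_select(g, 102, seed = 1), "exceeds")

  ppm10 <- c(-4.8, -3.8, -3.2, -0.7, -0.1, 0.0, 0.1, 1.1, 3.5, 4.5)
  f <- fixed_select(g, ppm10)
  expect_length(f$indices, 10)
  expect_equal(f$ppm, ppm10)
  expect_error(fixed_select(g, numeric(0)), "empty")
  expect_error(fixed_select(g, c(0, 0.25)), "not on grid")
})
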