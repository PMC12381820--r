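# Shared fixture builders; everything is generated in code at test time.

grid51 <- function() make_offset_grid(-5, 5, 0.2)
grid101 <- function() make_offset_grid(-5, 5, 0.1)

# a heterogeneous family of mouse-brain-like spectra with jittered pool
# parameters; amplitude ranges sum to at most 0.99 so every draw is valid
jittered_pools <- function() {
  list(
    pool_spec(runif(1, 0.55, 0.69), 0.0, runif(1, 1.0, 1.8), "water"),
    pool_spec(runif(1, 0.02, 0.08), 3.5, runif(1, 0.7, 1.3), "amide"),
    pool_spec(runif(1, 0.03, 0.09), -3.5, runif(1, 1.4, 2.6), "noe"),
    pool_spec(runif(1, 0.04, 0.09), -1.0, runif(1, 5, 11), "mt"),
    pool_spec(runif(1, 0.00, 0.04), 2.0, runif(1, 0.8, 1.6), "amine")
  )
}

# matrix (n, length(grid)) of clean dense spectra with per-spectrum pool
# jitter and B0 scatter typical of a shimmed in vivo cohort
synthetic_corpus <- function(n, grid = grid101(), seed = 100, noise_sd = 0,
                             b0_sd = 0.15) {
  withr::with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      simulate_zspectrum(grid, jittered_pools(),
                         b0_shift = rnorm(1, 0, b0_sd),
                         noise_sd = noise_sd, seed = seed + i)$values
    }, numeric(length(grid))))
  })
}

synthetic_zspectra <- function(n, grid = grid101(), seed = 100) {
  zspectra(synthetic_corpus(n, grid, seed), grid)
}

mean_rmse_rows <- function(a, b) mean(sqrt(rowMeans((a - b)^2)))
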