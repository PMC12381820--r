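#' Sparse offset subset
#'
#' A candidate set of saturation offsets: `k` distinct, sorted indices into
#' a dense offset grid, the derived ppm values, and (once evaluated) the
#' spline-reconstruction RMSE used as GA fitness.
#'
#' @param indices distinct 1-based positions into `grid`.
#' @param grid the dense `offset_grid` the indices refer to.
#' @param fitness optional RMSE of the subset's spline reconstruction.
#' @return an `offset_subset` object with fields `indices`, `ppm`,
#'   `fitness`.
#' @export
offset_subset <- function(indices, grid, fitness = NA_real_) {
  grid <- as_offset_grid(grid)
  indices <- sort(as.integer(indices))
  if (anyDuplicated(indices)) stop("`indices` must be distinct")
  if (length(indices) < 1 || min(indices) < 1 || max(indices) > length(grid)) {
    stop("`indices` out of grid range")
  }
  structure(list(indices = indices, ppm = grid$offsets[indices],
                 grid = grid, fitness = as.numeric(fitness)),
            class = "offset_subset")
}

#' @export
print.offset_subset <- function(x, ...) {
  cat(sprintf("<offset_subset> %d of %d offsets%s\n  ppm: %s\n",
              length(x$indices), length(x$grid),
              if (is.na(x$fitness)) "" else sprintf(", fitness (RMSE) %.4g", x$fitness),
              paste(format(x$ppm, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' Cubic-spline reconstruction of a dense spectrum from sparse samples
#'
#' Interpolates the sparse values with a cubic spline (Forsythe-Malcolm-
#' Moler end conditions, which reproduce cubic polynomials exactly) and
#' evaluates it on the full grid.  Outside the hull of the selected offsets
#' the end values are extended as constants.
#'
#' @param subset an [offset_subset()] with at least 4 offsets.
#' @param sparse_values signal values at the subset offsets, same order.
#' @param full_grid the dense `offset_grid` to reconstruct on.
#' @return numeric vector of reconstructed values on `full_grid`; exact at
#'   the selected offsets.
#' @export
spline_reconstruct <- function(subset, sparse_values, full_grid) {
  stopifnot(inherits(subset, "offset_subset"))
  full_grid <- as_offset_grid(full_grid)
  if (length(subset$indices) < 4) {
    stop("cubic-spline reconstruction needs at least 4 offsets")
  }
  if (length(sparse_values) != length(subset$indices)) {
    stop("`sparse_values` must align with the subset")
  }
  xs <- subset$ppm
  f <- splinefun(xs, sparse_values, method = "fmm")
  xq <- pmin(pmax(full_grid$offsets, min(xs)), max(xs))
  f(xq)
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

#' Fitness of an offset subset: spline-reconstruction RMSE
#'
#' The loss minimised by the genetic search: sample the dense Z-spectrum at
#' the subset offsets, reconstruct the full spectrum by cubic spline, and
#' return the RMSE against the dense spectrum over all offsets.
#'
#' @param subset an [offset_subset()] over `dense$grid`.
#' @param dense the dense [zspectrum()].
#' @return RMSE (unitless, same scale as S/S0).
#' @export
subset_fitness <- function(subset, dense) {
  stopifnot(inherits(subset, "offset_subset"), inherits(dense, "zspectrum"))
  if (max(subset$indices) > length(dense$grid)) {
    stop("subset does not fit the dense grid")
  }
  recon <- spline_reconstruct(subset, dense$values[subset$indices], dense$grid)
  rmse(recon, dense$values)
}

#' Genetic-algorithm configuration
#'
#' @param population_size chromosomes per generation, at least 2.
#' @param mutation_rate per-gene replacement probability in `[0, 1]`.
#' @param max_generations generation budget.
#' @param target_loss RMSE at which the search stops early (`NULL` = none).
#' @param patience generations without best-fitness improvement (below
#'   1e-6) before the search is declared stalled.
#' @param elitism number of best chromosomes copied unchanged; 1 makes the
#'   per-generation best fitness monotone non-increasing.
#' @param tournament_size parents are the winners of fitness tournaments of
#'   this size.
#' @param seed integer RNG seed, required for reproducible selection.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population_size = 60, mutation_rate = 0.1,
                      max_generations = 300, target_loss = NULL,
                      patience = 20, elitism = 1, tournament_size = 3,
                      seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  stopifnot(population_size >= 2, mutation_rate >= 0, mutation_rate <= 1,
            max_generations >= 1, patience >= 1, elitism >= 0,
            tournament_size >= 1)
  structure(list(population_size = as.integer(population_size),
                 mutation_rate = mutation_rate,
                 max_generations = as.integer(max_generations),
                 target_loss = target_loss,
                 patience = as.integer(patience),
                 elitism = as.integer(elitism),
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# set-preserving crossover: pool both parents' genes, draw k distinct
crossover_subsets <- function(a, b, k) {
  u <- union(a, b)
  if (length(u) <= k) {
    # pad from outside (caller guarantees k <= N via mutation space); only
    # possible when parents overlap heavily
    u
  } else {
    sample(u, k)
  }
}

mutate_subset <- function(genes, n_total, rate) {
  hit <- runif(length(genes)) < rate
  if (!any(hit)) return(genes)
  pool <- setdiff(seq_len(n_total), genes)
  n_hit <- sum(hit)
  if (length(pool) == 0) return(genes)
  genes[hit] <- sample(pool, min(n_hit, length(pool)))
  unique(genes)
}

complete_subset <- function(genes, k, n_total) {
  if (length(genes) < k) {
    genes <- c(genes, sample(setdiff(seq_len(n_total), genes),
                             k - length(genes)))
  }
  sort(genes)
}

#' Genetic-algorithm selection of optimal sparse offsets
#'
#' Searches for the `k = round(p% * N)`-offset subset of the dense grid that
#' minimises the cubic-spline reconstruction RMSE ([subset_fitness()]) of
#' the given dense Z-spectrum.  Chromosomes are fixed-cardinality index
#' sets; parents are picked by fitness tournaments, recombined by pooling
#' both parents' genes and drawing `k` distinct ones, and mutated by
#' replacing genes with unselected offsets.  The best chromosome is carried
#' over unchanged (elitism), so the recorded best fitness never increases.
#' The search stops when a target loss is reached, when the best fitness
#' has not improved for `patience` consecutive generations, or at the
#' generation budget.
#'
#' @param dense the dense [zspectrum()] to optimise against.
#' @param p selection budget as a percentage of the grid size (10 keeps 10
#'   of 101 offsets).
#' @param config a [ga_config()].
#' @param k subset cardinality, overriding `p` when given directly.
#' @return a `ga_result`: `best` ([offset_subset()] with fitness),
#'   `history` (best population fitness per generation), `generations_run`,
#'   and `termination_reason` (`"target_reached"`, `"stalled"`, or
#'   `"max_generations"`).
#' @export
ga_select <- function(dense, p = 10, config = ga_config(seed = 1),
                      k = NULL) {
  stopifnot(inherits(dense, "zspectrum"), inherits(config, "ga_config"))
  n <- length(dense$grid)
  if (is.null(k)) k <- as.integer(round(p / 100 * n))
  if (k < 4) stop("subset cardinality must be at least 4 (cubic spline)")
  if (k > n) stop("subset cardinality exceeds the grid size")

  xs_full <- dense$grid$offsets
  ys_full <- dense$values
  eval_fit <- function(genes) {
    xs <- xs_full[genes]
    f <- splinefun(xs, ys_full[genes], method = "fmm")
    recon <- f(pmin(pmax(xs_full, xs[1]), xs[k]))
    sqrt(mean((recon - ys_full)^2))
  }

  with_seed(config$seed, {
    pop <- replicate(config$population_size,
                     sort(sample.int(n, k)), simplify = FALSE)
    fit <- vapply(pop, eval_fit, numeric(1))
    best_idx <- which.min(fit)
    best_genes <- pop[[best_idx]]
    best_fit <- fit[best_idx]
    history <- numeric(0)
    stall <- 0L
    reason <- "max_generations"
    gens <- 0L

    for (g in seq_len(config$max_generations)) {
      gens <- g
      ord <- order(fit)
      new_pop <- pop[ord[seq_len(min(config$elitism, length(pop)))]]
      while (length(new_pop) < config$population_size) {
        pa <- pop[[tournament_pick(fit, config$tournament_size)]]
        pb <- pop[[tournament_pick(fit, config$tournament_size)]]
        child <- crossover_subsets(pa, pb, k)
        child <- mutate_subset(child, n, config$mutation_rate)
        new_pop[[length(new_pop) + 1L]] <- complete_subset(child, k, n)
      }
      pop <- new_pop
      fit <- vapply(pop, eval_fit, numeric(1))
      gen_best <- min(fit)
      history <- c(history, gen_best)
      improved <- best_fit - gen_best
      if (gen_best < best_fit) {
        best_fit <- gen_best
        best_genes <- pop[[which.min(fit)]]
      }
      if (improved > 1e-6) stall <- 0L else stall <- stall + 1L
      if (!is.null(config$target_loss) && best_fit <= config$target_loss) {
        reason <- "target_reached"
        break
      }
      if (stall >= config$patience) {
        reason <- "stalled"
        break
      }
    }

    structure(list(best = offset_subset(best_genes, dense$grid, best_fit),
                   history = history,
                   generations_run = gens,
                   termination_reason = reason),
              class = "ga_result")
  })
}

tournament_pick <- function(fit, size) {
  cand <- sample.int(length(fit), min(size, length(fit)))
  cand[which.min(fit[cand])]
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best RMSE %.4g after %d generations (%s)\n",
              x$best$fitness, x$generations_run, x$termination_reason))
  print(x$best)
  invisible(x)
}

#' Choose the best candidate subset across per-spectrum GA runs
#'
#' The search is run once per dense spectrum; the final acquisition scheme
#' is then the candidate that reconstructs best.  `"own"` ranks each
#' candidate by its fitness on the spectrum it was optimised for;
#' `"cross-mean"` re-evaluates every candidate on every spectrum and ranks
#' by mean RMSE.
#'
#' @param candidates list of `ga_result` (or [offset_subset()]) objects.
#' @param spectra list of [zspectrum()] (or a [zspectra()] table); in
#'   `"own"` mode one per candidate.
#' @param mode `"own"` (default) or `"cross-mean"`.
#' @return the winning [offset_subset()]; in `"cross-mean"` mode its
#'   `fitness` is the mean RMSE across spectra.
#' @export
select_best_candidate <- function(candidates, spectra = NULL,
                                  mode = c("own", "cross-mean")) {
  mode <- match.arg(mode)
  if (length(candidates) == 0) stop("`candidates` is empty")
  subsets <- lapply(candidates, function(cand) {
    if (inherits(cand, "ga_result")) cand$best else cand
  })
  if (inherits(spectra, "zspectra")) {
    spectra <- lapply(seq_len(nrow(spectra)), function(i) get_spectrum(spectra, i))
  }
  if (mode == "own") {
    if (!is.null(spectra)) {
      if (length(spectra) != length(subsets)) {
        stop("`own` mode needs one spectrum per candidate")
      }
      fits <- mapply(function(su, sp) subset_fitness(su, sp), subsets, spectra)
    } else {
      fits <- vapply(subsets, `[[`, numeric(1), "fitness")
      if (anyNA(fits)) stop("candidates lack fitness; supply `spectra`")
    }
    return(subsets[[which.min(fits)]])
  }
  if (is.null(spectra) || length(spectra) == 0) {
    stop("`cross-mean` mode needs evaluation spectra")
  }
  mean_fit <- vapply(subsets, function(su) {
    mean(vapply(spectra, function(sp) subset_fitness(su, sp), numeric(1)))
  }, numeric(1))
  win <- subsets[[which.min(mean_fit)]]
  win$fitness <- min(mean_fit)
  win
}

#' Baseline selector: uniform pseudo-random offsets
#'
#' Draws `k` distinct offsets uniformly without replacement — the PRNG
#' baseline the optimised selection is compared against.
#'
#' @param grid the dense `offset_grid`.
#' @param k number of offsets, at most the grid size.
#' @param seed integer seed.
#' @return an [offset_subset()] (fitness unset).
#' @export
prng_select <- function(grid, k, seed = NULL) {
  grid <- as_offset_grid(grid)
  if (k > length(grid)) stop("`k` exceeds the grid size")
  idx <- with_seed(seed, sample.int(length(grid), k))
  offset_subset(idx, grid)
}

#' Baseline selector: a fixed user-supplied ppm list
#'
#' Wraps an externally chosen offset list (e.g. a published empirical
#' scheme) as a subset; every ppm value must match a grid point within
#' 1e-6 ppm.
#'
#' @param grid the dense `offset_grid`.
#' @param ppm_list non-empty numeric ppm values.
#' @return an [offset_subset()] at the matching indices.
#' @export
fixed_select <- function(grid, ppm_list) {
  grid <- as_offset_grid(grid)
  if (length(ppm_list) == 0) stop("`ppm_list` is empty")
  offset_subset(grid_index(grid, ppm_list), grid)
}
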