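#' Experiment configuration
#'
#' Bundles the simulation, selection, training and evaluation settings of a
#' full synthetic experiment.  Every stochastic stage derives its own seed
#' deterministically from `seed`, so a rerun with the same configuration
#' reproduces the same subsets, weights and metrics.
#'
#' @param seed global integer seed.
#' @param out_dir output directory for artifacts.
#' @param simulation list: `n_subjects`, `n_slices`, `shape`, `noise_sd`,
#'   `b0_sd` (per-pixel B0 field sd in ppm), `grid` (`c(start, stop,
#'   step)`), `dense_step`.
#' @param ga list passed to [ga_config()] plus `p` (percent budget, may be
#'   a vector) and `mode` for [select_best_candidate()].
#' @param training list: `architecture`, `channels`, `epochs`,
#'   `batch_size`, `n_copies` (Gaussian augmentation copies),
#'   `n_test` (held-out slice averages).
#' @param ... reserved.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(seed = 1, out_dir = tempfile("zspeed-"),
                              simulation = list(), ga = list(),
                              training = list(), ...) {
  sim <- modifyList(list(n_subjects = 19, n_slices = 2, shape = c(48, 48),
                         noise_sd = 0.01, b0_sd = 0.1,
                         grid = c(-5, 5, 0.2), dense_step = 0.1), simulation)
  ga <- modifyList(list(p = 10, population_size = 60, mutation_rate = 0.1,
                        max_generations = 300, patience = 20,
                        mode = "own"), ga)
  tr <- modifyList(list(architecture = "autoencoder", channels = c(16, 32),
                        epochs = 60, batch_size = 16, n_copies = 20,
                        n_test = 8), training)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulation = sim, ga = ga, training = tr),
            class = "experiment_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

stage_seed <- function(seed, stage) {
  # deterministic per-stage seeds, kept well inside 32-bit range
  (seed * 101L + stage * 7919L) %% 2000000011L
}

#' Run the full synthetic acceleration experiment
#'
#' Orchestrates the pipeline end to end: simulate a phantom cohort ->
#' slice-average dense spectra, resampled to the dense grid -> GA offset
#' selection at each requested budget -> Gaussian-augmented training set ->
#' network training -> reconstruction of held-out spectra -> metrics.
#' Every intermediate artifact (spectra CSVs, subset JSONs, training
#' history CSV, reconstruction CSV, report JSON) is written under
#' `config$out_dir`, each stamped with the global seed and a configuration
#' hash.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-stage progress?
#' @return the experiment report (named list), invisibly also written to
#'   `report.json`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  hash <- config_hash(config)

  # -- simulate ------------------------------------------------------------
  sim <- config$simulation
  acq_grid <- make_offset_grid(sim$grid[1], sim$grid[2], sim$grid[3])
  dense_grid <- make_offset_grid(sim$grid[1], sim$grid[2], sim$dense_step)
  b0_field <- with_seed(stage_seed(config$seed, 1L),
    matrix(rnorm(prod(sim$shape), 0, sim$b0_sd), sim$shape[1], sim$shape[2]))
  say("simulate: %d subjects x %d slices", sim$n_subjects, sim$n_slices)
  vols <- simulate_phantom(sim$n_subjects, sim$n_slices, sim$shape,
                           b0_field = b0_field, grid = acq_grid,
                           noise_sd = sim$noise_sd,
                           seed = stage_seed(config$seed, 2L))

  # -- preprocess: B0 correction on slice averages, then resample ----------
  averages <- cohort_slice_averages(vols)
  corrected <- lapply(seq_len(nrow(averages)), function(i) {
    sp <- get_spectrum(averages, i)
    b0_correct(sp, estimate_water_center(sp))
  })
  dense <- resample_spectra(bind_spectra(corrected), dense_grid)
  write_zspectra_csv(dense, file.path(config$out_dir, "dense_spectra.csv"))

  n_test <- config$training$n_test
  if (nrow(dense) <= n_test) stop("not enough spectra for the held-out split")
  train_rows <- seq_len(nrow(dense) - n_test)
  test_rows <- setdiff(seq_len(nrow(dense)), train_rows)

  # -- select: GA per training spectrum, best candidate per budget ---------
  budgets <- config$ga$p
  ga_base <- config$ga[setdiff(names(config$ga), c("p", "mode"))]
  subsets <- list()
  for (p in budgets) {
    say("select: GA at p = %d%%", p)
    results <- lapply(train_rows, function(i) {
      cfg <- do.call(ga_config, c(ga_base,
        list(seed = stage_seed(config$seed, 10L + i + 1000L * p))))
      ga_select(get_spectrum(dense, i), p = p, config = cfg)
    })
    best <- select_best_candidate(
      results,
      spectra = lapply(train_rows, function(i) get_spectrum(dense, i)),
      mode = config$ga$mode)
    subsets[[as.character(p)]] <- best
    write_subset_json(best, file.path(config$out_dir,
                                      sprintf("subset_p%02d.json", p)))
  }

  # -- train + reconstruct + evaluate per budget ---------------------------
  trcfg <- config$training
  aug <- augment_gaussian(zspectra(zs_values(dense)[train_rows, , drop = FALSE],
                                   dense_grid),
                          n_copies = trcfg$n_copies,
                          seed = stage_seed(config$seed, 3L))
  test_vals <- zs_values(dense)[test_rows, , drop = FALSE]
  report_budgets <- list()
  for (p in budgets) {
    subset <- subsets[[as.character(p)]]
    say("train: %s at p = %d%%", trcfg$architecture, p)
    spec <- model_spec(trcfg$architecture, input_length = length(dense_grid),
                       channels = trcfg$channels)
    model <- build_model(spec, seed = stage_seed(config$seed, 20L + p))
    model <- train_model(model,
                         encode_sparse(aug, subset), zs_values(aug),
                         train_config(epochs = trcfg$epochs,
                                      batch_size = trcfg$batch_size,
                                      seed = stage_seed(config$seed, 30L + p)))
    utils::write.csv(model$history,
                     file.path(config$out_dir, sprintf("history_p%02d.csv", p)),
                     row.names = FALSE)
    recon <- predict(model, encode_sparse(test_vals, subset), clip = TRUE)
    write_zspectra_csv(zspectra(recon, dense_grid),
                       file.path(config$out_dir,
                                 sprintf("reconstruction_p%02d.csv", p)))
    rep <- metrics_report(recon, test_vals)
    spline_recon <- t(vapply(seq_len(nrow(test_vals)), function(i) {
      spline_reconstruct(subset, test_vals[i, subset$indices], dense_grid)
    }, numeric(ncol(test_vals))))
    spline_rep <- metrics_report(spline_recon, test_vals)
    report_budgets[[as.character(p)]] <- list(
      p = p,
      subset_ppm = subset$ppm,
      subset_fitness = subset$fitness,
      n_offsets = length(subset$indices),
      acceleration = acceleration(length(dense_grid), length(subset$indices)),
      model_rmse = rep$summary[rep$summary$metric == "rmse", ],
      spline_rmse = spline_rep$summary[spline_rep$summary$metric == "rmse", ],
      metrics = rep$summary)
  }

  report <- list(
    seed = config$seed,
    config_hash = hash,
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("zspeed")),
    n_spectra = nrow(dense),
    n_train = length(train_rows), n_test = n_test,
    budgets = report_budgets,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", force = TRUE)
  # manifest stamps every artifact with the seed and config hash
  jsonlite::write_json(
    list(seed = config$seed, config_hash = hash,
         files = setdiff(list.files(config$out_dir), "manifest.json")),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(report)
}
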