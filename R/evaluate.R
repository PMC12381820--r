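#' Spectrum reconstruction metrics
#'
#' RMSE, MAE and Pearson correlation between a reconstructed and a
#' reference Z-spectrum.  RMSE weights large errors more heavily; MAE gives
#' the typical per-offset error; Pearson r measures how well the spectral
#' shape is retained.
#'
#' @param reconstructed,reference equal-length numeric vectors (length at
#'   least 2); the reference must not be constant (r undefined).
#' @return named list `rmse`, `mae`, `pearson`.
#' @export
spectrum_metrics <- function(reconstructed, reference) {
  if (length(reconstructed) != length(reference)) stop("length mismatch")
  if (length(reference) < 2) stop("need at least 2 points")
  if (sd(reference) == 0) stop("Pearson r undefined for a constant reference")
  err <- reconstructed - reference
  list(rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)),
       pearson = cor(reconstructed, reference))
}

#' Per-spectrum metrics table with summary
#'
#' Applies [spectrum_metrics()] row-wise to matched tables of reconstructed
#' and reference spectra and appends min/max/mean summaries.
#'
#' @param reconstructed,reference numeric matrices (rows = spectra) or
#'   [zspectra()] tables of identical shape.
#' @return list with `per_spectrum` (data frame: spectrum, rmse, mae,
#'   pearson) and `summary` (data frame: metric, min, max, mean).
#' @export
metrics_report <- function(reconstructed, reference) {
  A <- if (inherits(reconstructed, "zspectra")) zs_values(reconstructed) else rbind(reconstructed)
  B <- if (inherits(reference, "zspectra")) zs_values(reference) else rbind(reference)
  stopifnot(all(dim(A) == dim(B)))
  per <- do.call(rbind, lapply(seq_len(nrow(A)), function(i) {
    m <- spectrum_metrics(A[i, ], B[i, ])
    data.frame(spectrum = i, rmse = m$rmse, mae = m$mae, pearson = m$pearson)
  }))
  summ <- do.call(rbind, lapply(c("rmse", "mae", "pearson"), function(k) {
    data.frame(metric = k, min = min(per[[k]]), max = max(per[[k]]),
               mean = mean(per[[k]]))
  }))
  list(per_spectrum = per, summary = summ)
}

#' MTR map of one slice
#'
#' Magnetization transfer ratio at a solute offset (default 3.5 ppm, the
#' amide resonance).  `"asym"` computes the asymmetry `Z(-ppm) - Z(+ppm)`,
#' cancelling symmetric direct saturation; `"one-minus-Z"` computes
#' `1 - Z(+ppm)`.  Off-grid ppm values are linearly interpolated.
#'
#' @param volume a [cest_volume()].
#' @param ppm solute offset in ppm; both `+ppm` and `-ppm` must lie within
#'   the grid.
#' @param slice_index slice number (1-based).
#' @param mode `"asym"` (default) or `"one-minus-Z"`.
#' @return numeric `nx x ny` matrix (`NA` outside the mask) with attribute
#'   `"mode"` recording the convention used.
#' @export
mtr_map <- function(volume, ppm = 3.5, slice_index = 1,
                    mode = c("asym", "one-minus-Z")) {
  stopifnot(inherits(volume, "cest_volume"))
  mode <- match.arg(mode)
  x <- volume$grid$offsets
  if (ppm > max(x) + 1e-9 || -ppm < min(x) - 1e-9) {
    stop("`ppm` outside the offset grid")
  }
  d <- dim(volume$data)
  slice <- matrix(volume$data[, , slice_index, ], ncol = d[4])
  interp_at <- function(p) {
    # linear interpolation weights on the uniform grid
    apply(slice, 1, function(v) approx(x, v, xout = p, rule = 2)$y)
  }
  zp <- interp_at(ppm)
  map <- if (mode == "asym") interp_at(-ppm) - zp else 1 - zp
  out <- matrix(map, d[1], d[2])
  out[!volume$mask] <- NA_real_
  attr(out, "mode") <- mode
  out
}

gaussian_kernel_1d <- function(size = 7, sigma = 1.5) {
  half <- (size - 1) / 2
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable 2D filtering with edge replication
filter2_sep <- function(M, k) {
  half <- (length(k) - 1) / 2
  n <- nrow(M); m <- ncol(M)
  idx <- function(i, lim) pmin(pmax(i, 1), lim)
  out <- matrix(0, n, m)
  for (j in -half:half) out <- out + k[j + half + 1] * M[idx(seq_len(n) + j, n), , drop = FALSE]
  out2 <- matrix(0, n, m)
  for (j in -half:half) out2 <- out2 + k[j + half + 1] * out[, idx(seq_len(m) + j, m), drop = FALSE]
  out2
}

#' Map quality metrics: PSNR, MAE, SSIM
#'
#' PSNR is `10 log10(range^2 / MSE)` (infinite for identical maps); SSIM
#' uses the standard constants `K1 = 0.01`, `K2 = 0.03` with a 7x7 Gaussian
#' window (sigma 1.5) and edge-replicated local statistics.
#'
#' @param test_map,reference_map numeric matrices of identical shape; `NA`
#'   pixels (outside a mask) must coincide and are ignored.
#' @param data_range declared dynamic range (1.0 for normalized maps).
#' @return named list `psnr` (dB), `mae`, `ssim`.
#' @export
map_metrics <- function(test_map, reference_map, data_range = 1) {
  stopifnot(all(dim(test_map) == dim(reference_map)))
  na_t <- is.na(test_map); na_r <- is.na(reference_map)
  if (!identical(na_t, na_r)) stop("NA patterns of the maps differ")
  if (any(na_t)) {  # fill masked-out pixels identically so they cancel
    test_map[na_t] <- 0
    reference_map[na_r] <- 0
  }
  ok <- !na_t
  mse <- mean((test_map[ok] - reference_map[ok])^2)
  mae <- mean(abs(test_map[ok] - reference_map[ok]))
  psnr <- if (mse == 0) Inf else 10 * log10(data_range^2 / mse)

  k <- gaussian_kernel_1d(7, 1.5)
  mu1 <- filter2_sep(test_map, k)
  mu2 <- filter2_sep(reference_map, k)
  s11 <- filter2_sep(test_map^2, k) - mu1^2
  s22 <- filter2_sep(reference_map^2, k) - mu2^2
  s12 <- filter2_sep(test_map * reference_map, k) - mu1 * mu2
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  ssim_map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  list(psnr = psnr, mae = mae, ssim = mean(ssim_map[ok]))
}

#' Acquisition parameters of a RARE-readout CEST scan
#'
#' @param tr repetition time in seconds.
#' @param n_pe number of phase-encoding lines.
#' @param etl echo train length; at most `n_pe`.
#' @param n_offs number of saturation offsets acquired.
#' @return an `acquisition_params` object.
#' @export
acquisition_params <- function(tr, n_pe, etl, n_offs) {
  stopifnot(tr > 0, n_pe > 0, etl > 0, n_offs > 0)
  if (etl > n_pe) stop("`etl` cannot exceed `n_pe`")
  structure(list(tr = tr, n_pe = n_pe, etl = etl, n_offs = n_offs),
            class = "acquisition_params")
}

#' Total acquisition time
#'
#' `T_A = TR * (N_PE / ETL) * N_offs`: scan time grows linearly with the
#' number of saturation offsets, which is what sparse offset selection
#' exploits.
#'
#' @param params an [acquisition_params()].
#' @return acquisition time in seconds.
#' @export
acquisition_time <- function(params) {
  stopifnot(inherits(params, "acquisition_params"))
  params$tr * (params$n_pe / params$etl) * params$n_offs
}

#' Acceleration factor from offset reduction
#'
#' With TR, phase encoding and echo train fixed, acquisition time is
#' proportional to the offset count, so the fold speed-up is simply
#' `n_full / n_sparse` (101 -> 10 offsets gives 10.1x).
#'
#' @param n_full,n_sparse offset counts of the dense and sparse schemes.
#' @return the fold reduction in acquisition time.
#' @export
acceleration <- function(n_full, n_sparse) {
  if (n_full <= 0 || n_sparse <= 0) stop("offset counts must be positive")
  n_full / n_sparse
}
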