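#' Saturation pool specification
#'
#' One saturating pool contributing a Lorentzian dip to the Z-spectrum:
#' direct water saturation, an exchanging solute pool (amide, amine), a
#' relayed NOE pool, or the broad semi-solid MT background.
#'
#' @param amplitude unitless dip depth at the pool centre, in `[0, 1]`.
#' @param center pool resonance in ppm from water.
#' @param fwhm full width at half maximum in ppm, positive.
#' @param name optional label.
#' @return a `pool_spec` object.
#' @export
pool_spec <- function(amplitude, center, fwhm, name = NULL) {
  stopifnot(is.numeric(amplitude), is.numeric(center), is.numeric(fwhm))
  if (amplitude < 0) stop("`amplitude` must be non-negative")
  if (fwhm <= 0) stop("`fwhm` must be positive")
  structure(list(amplitude = amplitude, center = center, fwhm = fwhm,
                 name = name), class = "pool_spec")
}

#' Default mouse-brain-like pool set
#'
#' Five pools whose superposition gives a Z-spectrum with the qualitative
#' shape of in vivo mouse brain at 7 T / 2 uT saturation: a deep direct
#' water-saturation dip at 0 ppm, an amide (APT) dip at +3.5 ppm, a relayed
#' NOE dip at -3.5 ppm, a broad slightly downfield-shifted semi-solid MT
#' background, and a small amine dip at +2 ppm.  Amplitudes sum to 0.99 so
#' that noise-free simulated signals stay non-negative everywhere.  These
#' values are plausible defaults for synthetic work, not a calibration to
#' any measured dataset.
#'
#' @return list of [pool_spec()] objects.
#' @export
default_pools <- function() {
  list(
    pool_spec(0.75, 0.0, 1.4, "water"),
    pool_spec(0.05, 3.5, 1.0, "amide"),
    pool_spec(0.06, -3.5, 2.0, "noe"),
    pool_spec(0.10, -1.0, 8.0, "mt"),
    pool_spec(0.03, 2.0, 1.2, "amine")
  )
}

#' Evaluate one Lorentzian pool on an offset grid
#'
#' Standard lineshape `A * (G/2)^2 / ((G/2)^2 + (x - c)^2)` with `A` the
#' amplitude, `c` the centre and `G` the FWHM; equals `A` at the centre and
#' `A/2` at `c +/- G/2`.
#'
#' @param grid an `offset_grid`.
#' @param pool a [pool_spec()].
#' @return numeric saturation vector in `[0, amplitude]`, one value per
#'   offset.
#' @export
lorentzian_pool <- function(grid, pool) {
  grid <- as_offset_grid(grid)
  stopifnot(inherits(pool, "pool_spec"))
  hw2 <- (pool$fwhm / 2)^2
  pool$amplitude * hw2 / (hw2 + (grid$offsets - pool$center)^2)
}

pool_sum <- function(x, pools, b0_shift = 0) {
  out <- numeric(length(x))
  for (p in pools) {
    hw2 <- (p$fwhm / 2)^2
    out <- out + p$amplitude * hw2 / (hw2 + (x - b0_shift - p$center)^2)
  }
  out
}

check_pools <- function(pools) {
  stopifnot(is.list(pools))
  for (p in pools) stopifnot(inherits(p, "pool_spec"))
  amp <- sum(vapply(pools, `[[`, numeric(1), "amplitude"))
  if (amp > 1 + 1e-9) {
    stop(sprintf("pool amplitudes sum to %.3f; must not exceed 1", amp))
  }
  invisible(amp)
}

#' Simulate one Z-spectrum from a multi-pool Lorentzian model
#'
#' The noise-free signal is `1 - sum of pool lineshapes` evaluated at
#' `offset - b0_shift`, so a positive `b0_shift` moves every dip (including
#' the water centre) towards positive ppm, as a positive B0 offset does in
#' vivo.  Additive white Gaussian noise is then applied.
#'
#' @param grid an `offset_grid`.
#' @param pools list of [pool_spec()]; amplitudes must sum to at most 1.
#' @param b0_shift apparent water-centre shift in ppm.
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   normalized signal (0.01 matches the augmentation noise level used for
#'   training data).
#' @param seed integer for reproducible noise; `NULL` uses the current RNG
#'   state.
#' @return a [zspectrum()].
#' @export
simulate_zspectrum <- function(grid, pools = default_pools(), b0_shift = 0,
                               noise_sd = 0, seed = NULL) {
  grid <- as_offset_grid(grid)
  check_pools(pools)
  clean <- 1 - pool_sum(grid$offsets, pools, b0_shift)
  vals <- if (noise_sd > 0) {
    with_seed(seed, clean + rnorm(length(clean), 0, noise_sd))
  } else clean
  # noise can push slightly outside [0, 1]; keep within container tolerance
  zspectrum(pmin(pmax(vals, 0), 1.05), grid)
}

#' Simulate a cohort of 4D CEST phantoms
#'
#' Builds `n_subjects` four-dimensional volumes (x, y, slice, offset) whose
#' per-pixel Z-spectra follow [simulate_zspectrum()] with per-pixel pool and
#' B0 fields, emulating a small-animal cohort (e.g. 19 mice, two brain
#' slices each) so slice-average spectra and pixel-subsample augmentation
#' can be exercised without scanner data.
#'
#' @param n_subjects,n_slices cohort dimensions.
#' @param shape spatial dimensions `c(nx, ny)` in pixels.
#' @param pool_field either a list of [pool_spec()] applied uniformly, or a
#'   function `(x, y, slice) -> list of pool_spec` for spatial structure.
#' @param b0_field per-pixel water shift: scalar, `nx x ny` matrix, or
#'   function `(x, y, slice) -> ppm`.
#' @param grid acquisition `offset_grid`.
#' @param noise_sd additive Gaussian noise sd per pixel sample.
#' @param mask `"rect"` (all pixels) or `"ellipse"` (inscribed ellipse, a
#'   stand-in for brain segmentation).
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @return list of [cest_volume()] objects, one per subject.
#' @export
simulate_phantom <- function(n_subjects = 19, n_slices = 2, shape = c(48, 48),
                             pool_field = default_pools(), b0_field = 0,
                             grid = make_offset_grid(-5, 5, 0.2),
                             noise_sd = 0, mask = c("ellipse", "rect"),
                             seed = NULL) {
  grid <- as_offset_grid(grid)
  mask <- match.arg(mask)
  stopifnot(n_subjects >= 1, n_slices >= 1, length(shape) == 2)
  nx <- shape[1]; ny <- shape[2]

  mask_mat <- if (mask == "rect") {
    matrix(TRUE, nx, ny)
  } else {
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    outer(seq_len(nx), seq_len(ny),
          function(i, j) ((i - cx) / (nx / 2))^2 + ((j - cy) / (ny / 2))^2 <= 1)
  }

  pools_at <- if (is.function(pool_field)) pool_field else function(x, y, s) pool_field
  b0_at <- if (is.function(b0_field)) {
    b0_field
  } else if (is.matrix(b0_field)) {
    if (!all(dim(b0_field) == shape)) stop("`b0_field` matrix must match `shape`")
    function(x, y, s) b0_field[x, y]
  } else {
    function(x, y, s) b0_field
  }

  n_off <- length(grid)
  lapply(seq_len(n_subjects), function(subj) {
    arr <- array(NA_real_, dim = c(nx, ny, n_slices, n_off))
    for (s in seq_len(n_slices)) {
      for (j in seq_len(ny)) {
        for (i in seq_len(nx)) {
          if (!mask_mat[i, j]) next
          pl <- pools_at(i, j, s)
          check_pools(pl)
          arr[i, j, s, ] <- 1 - pool_sum(grid$offsets, pl, b0_at(i, j, s))
        }
      }
    }
    if (noise_sd > 0) {
      arr <- with_seed(if (is.null(seed)) NULL else seed + subj,
                       arr + rnorm(length(arr), 0, noise_sd))
    }
    arr[arr < 0] <- 0; arr[arr > 1.05] <- 1.05
    cest_volume(arr, grid, mask = mask_mat)
  })
}

#' Augment Z-spectra with additive white Gaussian noise
#'
#' Each input spectrum is replicated `n_copies` times with independent
#' Gaussian noise added to every value — the scheme used to expand ~30
#' slice-average spectra into a training table of 3000 rows.
#'
#' @param spectra a [zspectra()] table.
#' @param n_copies copies per input spectrum, at least 1.
#' @param noise_mean,noise_sd Gaussian noise parameters (defaults 0 / 0.01).
#' @param include_base prepend the unperturbed input rows?
#' @param seed integer for reproducibility.
#' @return a `zspectra` table with `nrow(spectra) * n_copies` rows (plus the
#'   base rows when `include_base`).
#' @export
augment_gaussian <- function(spectra, n_copies, noise_mean = 0,
                             noise_sd = 0.01, include_base = FALSE,
                             seed = NULL) {
  stopifnot(inherits(spectra, "zspectra"))
  if (nrow(spectra) == 0) stop("`spectra` is empty")
  if (n_copies < 1) stop("`n_copies` must be at least 1")
  vals <- zs_values(spectra)
  rep_vals <- vals[rep(seq_len(nrow(vals)), each = n_copies), , drop = FALSE]
  noisy <- with_seed(seed, rep_vals +
    rnorm(length(rep_vals), noise_mean, noise_sd))
  noisy <- pmin(pmax(noisy, 0), 1.05)
  out <- if (include_base) rbind(vals, noisy) else noisy
  zspectra(out, zs_grid(spectra))
}

#' Augment a volume by averaging random pixel subsamples
#'
#' For every slice and every requested subsample size, draws that many
#' in-mask pixels without replacement and averages their Z-spectra,
#' producing one spectrum per (slice, size) pair.  With the default 16 sizes
#' `seq(800, 1550, by = 50)`, a 38-slice cohort yields 608 spectra.
#'
#' @param volume a [cest_volume()].
#' @param sizes pixel counts per subsample; each must not exceed the mask
#'   size.
#' @param seed integer master seed; draws are independent per (slice, size).
#' @return a `zspectra` table with `n_slices * length(sizes)` rows, ordered
#'   slice-major.
#' @export
augment_subsample <- function(volume, sizes = seq(800, 1550, by = 50),
                              seed = NULL) {
  stopifnot(inherits(volume, "cest_volume"))
  n_pix <- sum(volume$mask)
  if (any(sizes > n_pix)) {
    stop(sprintf("subsample size exceeds the %d in-mask pixels", n_pix))
  }
  if (any(sizes < 1)) stop("subsample sizes must be positive")
  n_slices <- dim(volume$data)[3]
  n_off <- dim(volume$data)[4]
  idx_mask <- which(volume$mask)
  rows <- with_seed(seed, {
    out <- matrix(NA_real_, n_slices * length(sizes), n_off)
    r <- 1L
    for (s in seq_len(n_slices)) {
      slice <- matrix(volume$data[, , s, ], ncol = n_off)  # (nx*ny) x n_off
      for (sz in sizes) {
        pick <- sample(idx_mask, sz, replace = FALSE)
        out[r, ] <- colMeans(slice[pick, , drop = FALSE])
        r <- r + 1L
      }
    }
    out
  })
  zspectra(rows, volume$grid)
}
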