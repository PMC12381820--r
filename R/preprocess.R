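#' Estimate the water-centre (B0) shift of a Z-spectrum
#'
#' The direct water-saturation dip sits at 0 ppm in a perfectly shimmed
#' voxel; B0 inhomogeneity displaces it.  Two estimators are provided:
#' `"argmin-spline"` upsamples the spectrum with a cubic spline at 0.01 ppm
#' resolution and returns the minimizer (the WASSR-style estimate used on a
#' low-power water-only scan), and `"lorentzian-fit"` fits a single
#' Lorentzian `b - A * (G/2)^2 / ((G/2)^2 + (x - c)^2)` by least squares
#' within 1.5 ppm of the raw minimum and returns the fitted centre `c`
#' (the cross-validation route used on the CEST scan itself).
#'
#' @param spectrum a [zspectrum()] whose grid covers 0 ppm.
#' @param method `"argmin-spline"` (default) or `"lorentzian-fit"`.
#' @return estimated water-centre shift in ppm.
#' @export
estimate_water_center <- function(spectrum,
                                  method = c("argmin-spline", "lorentzian-fit")) {
  stopifnot(inherits(spectrum, "zspectrum"))
  method <- match.arg(method)
  x <- spectrum$grid$offsets
  y <- spectrum$values
  if (min(x) > 0 || max(x) < 0) stop("grid must cover the water dip at 0 ppm")

  if (method == "argmin-spline") {
    f <- splinefun(x, y, method = "fmm")
    fine <- seq(min(x), max(x), by = 0.01)
    i <- which.min(f(fine))
    if (i == 1L || i == length(fine)) {
      stop("no interior water minimum found")
    }
    return(fine[i])
  }

  # lorentzian-fit: window around the raw minimum
  x0 <- x[which.min(y)]
  win <- abs(x - x0) <= 1.5
  if (sum(win) < 4) stop("too few points around the water dip for a fit")
  xw <- x[win]; yw <- y[win]
  resid_fn <- function(p) {
    yw - (p[1] - p[2] * (p[3] / 2)^2 / ((p[3] / 2)^2 + (xw - p[4])^2))
  }
  fit <- minpack.lm::nls.lm(
    par = c(base = max(yw), amp = max(yw) - min(yw), fw = 1.2, ctr = x0),
    fn = resid_fn,
    lower = c(0, 0, 0.05, min(xw)), upper = c(1.2, 1.2, 10, max(xw)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  unname(fit$par["ctr"])
}

#' Shift-correct a Z-spectrum along the ppm axis
#'
#' Re-interpolates the spectrum at `offsets + shift` with a cubic spline, so
#' that after correcting with the estimated water-centre shift the direct
#' saturation dip sits at 0 ppm.  Beyond the acquired range the end values
#' are extended (no spline extrapolation).
#'
#' @param spectrum a [zspectrum()].
#' @param shift water-centre shift in ppm, `|shift|` less than half the grid
#'   range.
#' @return the corrected [zspectrum()] on the same grid.
#' @export
b0_correct <- function(spectrum, shift) {
  stopifnot(inherits(spectrum, "zspectrum"), is.numeric(shift))
  x <- spectrum$grid$offsets
  if (abs(shift) >= (max(x) - min(x)) / 2) {
    stop("`shift` exceeds half the grid range")
  }
  f <- splinefun(x, spectrum$values, method = "fmm")
  xq <- pmin(pmax(x + shift, min(x)), max(x))  # edge-value extension
  zspectrum(pmin(pmax(f(xq), 0), 1.05), spectrum$grid)
}

#' Resample a Z-spectrum onto a finer grid by linear interpolation
#'
#' The acquisition grid (51 points at 0.2 ppm) is linearly interpolated to
#' the dense reconstruction grid (101 points at 0.1 ppm).  Target offsets
#' shared with the source are preserved exactly.
#'
#' @param spectrum a [zspectrum()].
#' @param target an `offset_grid` lying within the source range.
#' @return a [zspectrum()] on `target`.
#' @export
resample_linear <- function(spectrum, target) {
  stopifnot(inherits(spectrum, "zspectrum"))
  target <- as_offset_grid(target)
  x <- spectrum$grid$offsets
  if (min(target$offsets) < min(x) - 1e-9 ||
      max(target$offsets) > max(x) + 1e-9) {
    stop("`target` grid must lie within the source range")
  }
  vals <- approx(x, spectrum$values, xout = target$offsets, rule = 2)$y
  zspectrum(vals, target)
}

#' Resample every spectrum of a table
#'
#' @param spectra a [zspectra()] table.
#' @param target target `offset_grid`.
#' @return a `zspectra` table on `target`.
#' @export
resample_spectra <- function(spectra, target) {
  stopifnot(inherits(spectra, "zspectra"))
  target <- as_offset_grid(target)
  vals <- zs_values(spectra)
  x <- zs_grid(spectra)$offsets
  out <- t(apply(vals, 1, function(v) approx(x, v, xout = target$offsets,
                                             rule = 2)$y))
  zspectra(out, target)
}

#' Estimate a per-pixel B0 map from a volume
#'
#' Applies [estimate_water_center()] to every in-mask pixel spectrum of one
#' slice, yielding the field map used for per-pixel correction.
#'
#' @param volume a [cest_volume()].
#' @param slice_index slice number (1-based).
#' @param method passed to [estimate_water_center()].
#' @return matrix of shifts in ppm (`NA` outside the mask).
#' @export
b0_map <- function(volume, slice_index, method = "argmin-spline") {
  stopifnot(inherits(volume, "cest_volume"))
  d <- dim(volume$data)
  out <- matrix(NA_real_, d[1], d[2])
  for (j in seq_len(d[2])) {
    for (i in seq_len(d[1])) {
      if (!volume$mask[i, j]) next
      sp <- zspectrum(pmin(pmax(volume$data[i, j, slice_index, ], 0), 1.05),
                      volume$grid)
      out[i, j] <- estimate_water_center(sp, method)
    }
  }
  out
}

#' Per-pixel B0 correction of a volume
#'
#' @param volume a [cest_volume()].
#' @param shifts per-pixel shift maps: `nx x ny` matrix applied to all
#'   slices, or `nx x ny x n_slices` array.
#' @return the corrected [cest_volume()].
#' @export
b0_correct_volume <- function(volume, shifts) {
  stopifnot(inherits(volume, "cest_volume"))
  d <- dim(volume$data)
  if (is.matrix(shifts)) shifts <- array(shifts, dim = c(d[1:2], d[3]))
  stopifnot(all(dim(shifts) == d[1:3]))
  out <- volume$data
  for (s in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      for (i in seq_len(d[1])) {
        if (!volume$mask[i, j]) next
        sp <- zspectrum(pmin(pmax(volume$data[i, j, s, ], 0), 1.05),
                        volume$grid)
        out[i, j, s, ] <- b0_correct(sp, shifts[i, j, s])$values
      }
    }
  }
  cest_volume(out, volume$grid, volume$mask)
}
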