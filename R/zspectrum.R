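#' Z-spectrum containers
#'
#' A `zspectrum` is one normalized Z-spectrum: signal S/S0 per offset of an
#' [make_offset_grid()] grid.  A `zspectra` object is a table of spectra
#' sharing one grid, stored as a numeric matrix (rows = spectra, columns =
#' offsets) with the grid attached — the in-memory form of the CSV layout
#' used for training data (header = ppm, one spectrum per row).
#'
#' @param values numeric vector (one spectrum) or matrix (rows = spectra).
#' @param grid an `offset_grid` (or numeric ppm vector) matching the columns.
#' @return `zspectrum()` returns a `zspectrum`; `zspectra()` a `zspectra`
#'   matrix.
#' @export
zspectrum <- function(values, grid) {
  grid <- as_offset_grid(grid)
  values <- as.numeric(values)
  if (length(values) != length(grid)) {
    stop("`values` length must equal the grid length")
  }
  if (!all(is.finite(values))) stop("Z-spectrum values must be finite")
  if (any(values < -0.05) || any(values > 1.05)) {
    stop("Z-spectrum values must lie in [0, 1] up to a 0.05 noise tolerance")
  }
  structure(list(grid = grid, values = values), class = "zspectrum")
}

#' @rdname zspectrum
#' @export
zspectra <- function(values, grid) {
  grid <- as_offset_grid(grid)
  values <- rbind(values)
  if (ncol(values) != length(grid)) {
    stop("`values` must have one column per grid offset")
  }
  structure(values, grid = grid, class = c("zspectra", class(values)))
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("<zspectrum> %d offsets, %.4g to %.4g ppm; min S/S0 %.3f at %+.2f ppm\n",
              length(x$grid), x$grid$offsets[1], max(x$grid$offsets),
              min(x$values), x$grid$offsets[which.min(x$values)]))
  invisible(x)
}

#' @export
print.zspectra <- function(x, ...) {
  cat(sprintf("<zspectra> %d spectra x %d offsets (%.4g to %.4g ppm)\n",
              nrow(x), ncol(x), zs_grid(x)$offsets[1], max(zs_grid(x)$offsets)))
  invisible(x)
}

#' Accessors for Z-spectrum containers
#'
#' @param x a `zspectrum` or `zspectra` object.
#' @param i spectrum (row) index for `get_spectrum()`.
#' @return `zs_grid()` the shared `offset_grid`; `zs_values()` the numeric
#'   matrix of signals; `get_spectrum()` the i-th row as a `zspectrum`.
#' @export
zs_grid <- function(x) {
  if (inherits(x, "zspectrum")) x$grid else attr(x, "grid")
}

#' @rdname zs_grid
#' @export
zs_values <- function(x) {
  if (inherits(x, "zspectrum")) rbind(x$values) else unclass(x)[, , drop = FALSE]
}

#' @rdname zs_grid
#' @export
get_spectrum <- function(x, i) {
  stopifnot(inherits(x, "zspectra"), i >= 1, i <= nrow(x))
  zspectrum(unclass(x)[i, ], zs_grid(x))
}

#' Stack Z-spectra sharing a grid into a table
#'
#' @param spectra list of `zspectrum` objects on identical grids.
#' @return a `zspectra` matrix.
#' @export
bind_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  grid <- spectra[[1]]$grid
  vals <- do.call(rbind, lapply(spectra, function(s) {
    stopifnot(inherits(s, "zspectrum"))
    if (max(abs(s$grid$offsets - grid$offsets)) > 1e-9) {
      stop("all spectra must share one grid")
    }
    s$values
  }))
  zspectra(vals, grid)
}
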