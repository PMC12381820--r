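#' Construct a uniform saturation-offset grid
#'
#' An offset grid is the ordered list of saturation-frequency offsets (in ppm
#' relative to water) at which a Z-spectrum is sampled.  The acquisition grid
#' used throughout the package runs from -5 to +5 ppm at 0.2 ppm (51 points)
#' and is resampled to 0.1 ppm (101 points) before reconstruction.
#'
#' @param start,stop range endpoints in ppm; `stop` must exceed `start`.
#' @param step grid spacing in ppm, positive; `(stop - start)` must be an
#'   integer multiple of `step` (within 1e-6 relative tolerance).
#' @return an `offset_grid` object: list with `offsets` (strictly ascending,
#'   uniformly spaced ppm values with exact endpoints) and `step`.
#' @examples
#' length(make_offset_grid(-5, 5, 0.2))  # 51 acquired offsets
#' length(make_offset_grid(-5, 5, 0.1))  # 101 dense offsets
#' @export
make_offset_grid <- function(start, stop, step) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (step <= 0) stop("`step` must be positive")
  if (stop <= start) stop("`stop` must be greater than `start`")
  n_steps <- (stop - start) / step
  if (abs(n_steps - round(n_steps)) > 1e-6 * max(1, abs(n_steps))) {
    stop("(stop - start) is not an integer multiple of `step`")
  }
  n <- as.integer(round(n_steps)) + 1L
  offsets <- seq(start, stop, length.out = n)
  new_offset_grid(offsets, step)
}

new_offset_grid <- function(offsets, step) {
  structure(list(offsets = as.numeric(offsets), step = as.numeric(step)),
            class = "offset_grid")
}

#' Coerce a numeric vector of ppm values to an offset grid
#'
#' Used when a grid arrives as a CSV header.  The vector must be strictly
#' ascending and uniformly spaced (within 1e-9 ppm).
#'
#' @param offsets numeric vector of ppm values.
#' @return an [make_offset_grid()] style `offset_grid`.
#' @export
as_offset_grid <- function(offsets) {
  if (inherits(offsets, "offset_grid")) return(offsets)
  offsets <- as.numeric(offsets)
  if (length(offsets) < 2L) stop("an offset grid needs at least 2 points")
  d <- diff(offsets)
  if (any(d <= 0)) stop("offsets must be strictly ascending")
  if (max(d) - min(d) > 1e-9) stop("offsets must be uniformly spaced")
  new_offset_grid(offsets, mean(d))
}

#' @export
length.offset_grid <- function(x) length(x$offsets)

#' @export
print.offset_grid <- function(x, ...) {
  cat(sprintf("<offset_grid> %d offsets, %.4g to %.4g ppm, step %.4g ppm\n",
              length(x$offsets), x$offsets[1], x$offsets[length(x$offsets)],
              x$step))
  invisible(x)
}

# nearest grid index of a ppm value; err if no grid point within tol
grid_index <- function(grid, ppm, tol = 1e-6) {
  i <- vapply(ppm, function(p) which.min(abs(grid$offsets - p)), integer(1))
  bad <- abs(grid$offsets[i] - ppm) > tol
  if (any(bad)) {
    stop(sprintf("ppm value(s) not on grid: %s",
                 paste(format(ppm[bad]), collapse = ", ")))
  }
  i
}
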