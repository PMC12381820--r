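#' 4D CEST volume
#'
#' Per-pixel Z-spectra for one subject: a 4D intensity array `P(x, y, slice,
#' offset)` of normalized signal S/S0, the offset grid of its 4th axis, and
#' a spatial mask marking tissue pixels (all indices 1-based).
#'
#' @param data 4D numeric array, dims `(nx, ny, n_slices, n_offsets)`;
#'   values finite in `[0, 1.05]` inside the mask, `NA` allowed outside.
#' @param grid `offset_grid` whose length matches the 4th dimension.
#' @param mask logical `nx x ny` matrix; defaults to all `TRUE`.
#' @return a `cest_volume` object.
#' @export
cest_volume <- function(data, grid, mask = NULL) {
  grid <- as_offset_grid(grid)
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (dim(data)[4] != length(grid)) {
    stop("4th dimension of `data` must equal the grid length")
  }
  if (is.null(mask)) mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  stopifnot(is.logical(mask), all(dim(mask) == dim(data)[1:2]))
  in_mask <- data[rep(mask, times = dim(data)[3] * dim(data)[4])]
  if (!all(is.finite(in_mask))) stop("in-mask intensities must be finite")
  if (any(in_mask < -1e-9) || any(in_mask > 1.05 + 1e-9)) {
    stop("in-mask intensities must be normalized to [0, 1.05]")
  }
  structure(list(data = data, grid = grid, mask = mask),
            class = "cest_volume")
}

#' @export
print.cest_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cest_volume> %d x %d pixels, %d slice(s), %d offsets; %d in-mask pixels\n",
              d[1], d[2], d[3], d[4], sum(x$mask)))
  invisible(x)
}

#' Average the Z-spectra of one slice
#'
#' Per-offset mean over all in-mask pixels of the slice — the "dense
#' Z-spectrum" representation of a brain slice used for offset optimisation
#' and model training.
#'
#' @param volume a [cest_volume()].
#' @param slice_index slice number (1-based).
#' @return a [zspectrum()] on the volume's grid.
#' @export
slice_average <- function(volume, slice_index) {
  stopifnot(inherits(volume, "cest_volume"))
  n_slices <- dim(volume$data)[3]
  if (slice_index < 1 || slice_index > n_slices) {
    stop(sprintf("`slice_index` must be in 1..%d", n_slices))
  }
  if (!any(volume$mask)) stop("mask is empty")
  n_off <- dim(volume$data)[4]
  slice <- matrix(volume$data[, , slice_index, ], ncol = n_off)
  vals <- colMeans(slice[which(volume$mask), , drop = FALSE])
  zspectrum(pmin(pmax(vals, 0), 1.05), volume$grid)
}

#' Slice averages of a whole cohort
#'
#' Convenience wrapper applying [slice_average()] to every slice of every
#' volume; 19 subjects x 2 slices give the 38 dense spectra of a full
#' cohort.
#'
#' @param volumes list of [cest_volume()].
#' @return a [zspectra()] table, subject-major then slice order.
#' @export
cohort_slice_averages <- function(volumes) {
  specs <- unlist(lapply(volumes, function(v) {
    lapply(seq_len(dim(v$data)[3]), function(s) slice_average(v, s))
  }), recursive = FALSE)
  bind_spectra(specs)
}
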