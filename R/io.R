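#' Read / write Z-spectra CSV tables
#'
#' The on-disk layout is the one used for training data: a comma-separated
#' UTF-8 file whose header row is the ppm offsets (ascending, '.' decimal)
#' and whose subsequent rows are one spectrum each.  Values round-trip at
#' full double precision and row order is preserved.
#'
#' @param path file path.
#' @param spectra a [zspectra()] table.
#' @return `read_zspectra_csv()` returns a `zspectra` table.
#' @export
read_zspectra_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE)
  offsets <- suppressWarnings(as.numeric(colnames(dt)))
  if (anyNA(offsets)) stop("header is not numeric ppm values")
  if (any(diff(offsets) <= 0)) stop("header ppm values must be ascending")
  vals <- as.matrix(dt)
  if (!is.numeric(vals) || anyNA(vals)) stop("non-numeric cells in spectra table")
  dimnames(vals) <- NULL
  zspectra(vals, as_offset_grid(offsets))
}

#' @rdname read_zspectra_csv
#' @export
write_zspectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "zspectra"))
  vals <- zs_values(spectra)
  dt <- data.table::as.data.table(vals)
  data.table::setnames(dt, format(zs_grid(spectra)$offsets, trim = TRUE,
                                  digits = 15))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read / write 4D CEST volumes as NIfTI + JSON sidecar
#'
#' Volumes are stored as NIfTI-1 with the offset index on the 4th axis.  A
#' JSON sidecar (`<stem>.json`) carries the ppm list of that axis and the
#' flattened spatial mask, so a round trip restores the full
#' [cest_volume()].
#'
#' @param path `.nii` or `.nii.gz` path.
#' @param volume a [cest_volume()].
#' @return `read_volume()` returns a `cest_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4) stop("expected a 4D NIfTI volume")
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("missing sidecar JSON: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (length(meta$ppm) != dim(arr)[4]) {
    stop(sprintf("sidecar lists %d ppm values but the volume has %d frames",
                 length(meta$ppm), dim(arr)[4]))
  }
  mask <- matrix(as.logical(meta$mask), dim(arr)[1], dim(arr)[2])
  arr[arr < 0] <- 0
  arr[!rep(mask, times = dim(arr)[3] * dim(arr)[4])] <- NA_real_
  cest_volume(arr, as_offset_grid(meta$ppm), mask)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "cest_volume"))
  arr <- volume$data
  arr[is.na(arr)] <- 0
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  jsonlite::write_json(
    list(ppm = volume$grid$offsets, mask = as.vector(volume$mask)),
    sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read / write an offset subset as JSON
#'
#' Stores the ppm list, grid indices, fitness, and (when present) the GA
#' fitness history.
#'
#' @param subset an [offset_subset()] or `ga_result`.
#' @param path JSON file path.
#' @param grid optional `offset_grid` overriding the one stored in `path`.
#' @return `read_subset_json()` returns an `offset_subset` (with attribute
#'   `"history"` when stored).
#' @export
write_subset_json <- function(subset, path) {
  history <- NULL
  if (inherits(subset, "ga_result")) {
    history <- subset$history
    subset <- subset$best
  }
  stopifnot(inherits(subset, "offset_subset"))
  jsonlite::write_json(
    list(ppm = subset$ppm, indices = subset$indices,
         fitness = subset$fitness, grid_offsets = subset$grid$offsets,
         history = history),
    path, auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_subset_json
#' @export
read_subset_json <- function(path, grid = NULL) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- as_offset_grid(grid %||% meta$grid_offsets)
  out <- offset_subset(meta$indices, grid,
                       fitness = meta$fitness %||% NA_real_)
  if (!is.null(meta$history) && length(meta$history) > 0) {
    attr(out, "history") <- as.numeric(meta$history)
  }
  out
}
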