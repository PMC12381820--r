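#' Specification of a 1D reconstruction network
#'
#' Three architectures map a zero-masked sparse Z-spectrum (length 101) to
#' the dense Z-spectrum of the same length:
#' \describe{
#'   \item{`autoencoder`}{6 convolution layers, 2 max-pooling and 2
#'     upsampling layers, no skip connections.}
#'   \item{`unet1`}{the same layer budget plus skip connections passing
#'     encoder feature maps to the decoder.}
#'   \item{`unet2`}{a deeper variant: 10 convolution layers (double-conv
#'     blocks), 2 max-pooling, 2 upsampling layers and 2 skip connections.}
#' }
#'
#' @param architecture `"autoencoder"`, `"unet1"` or `"unet2"`.
#' @param input_length spectrum length (default 101).
#' @param channels feature channels of the two encoder stages (the decoder
#'   mirrors them); default `c(32, 64)`.
#' @param kernel_size convolution kernel width; only 3 is supported.
#' @param in_channels 1 for plain zero-masked input, 2 to add a sampling
#'   mask channel.
#' @return a `model_spec` object.
#' @export
model_spec <- function(architecture = c("autoencoder", "unet1", "unet2"),
                       input_length = 101, channels = c(32, 64),
                       kernel_size = 3, in_channels = 1) {
  architecture <- match.arg(architecture)
  stopifnot(input_length >= 8, length(channels) == 2, all(channels >= 1),
            in_channels %in% 1:2)
  if (kernel_size != 3) stop("only kernel size 3 is supported")
  structure(list(architecture = architecture,
                 input_length = as.integer(input_length),
                 channels = as.integer(channels),
                 kernel_size = 3L,
                 in_channels = as.integer(in_channels)),
            class = "model_spec")
}

build_ops <- function(spec) {
  c1 <- spec$channels[1]
  c2 <- spec$channels[2]
  cin <- spec$in_channels
  sv <- function(name) list(type = "save", name = name)
  cc <- function(name) list(type = "concat", name = name)
  pool <- list(type = "pool")
  up <- list(type = "up")
  switch(spec$architecture,
    autoencoder = list(
      nn_conv_op(cin, c1), pool,
      nn_conv_op(c1, c2), pool,
      nn_conv_op(c2, c2), up,
      nn_conv_op(c2, c1), up,
      nn_conv_op(c1, c1),
      nn_conv_op(c1, 1, act = "linear")
    ),
    unet1 = list(
      nn_conv_op(cin, c1), sv("s1"), pool,
      nn_conv_op(c1, c2), sv("s2"), pool,
      nn_conv_op(c2, c2), up, cc("s2"),
      nn_conv_op(2 * c2, c1), up, cc("s1"),
      nn_conv_op(2 * c1, c1),
      nn_conv_op(c1, 1, act = "linear")
    ),
    unet2 = list(
      nn_conv_op(cin, c1),
      nn_conv_op(c1, c1), sv("s1"), pool,
      nn_conv_op(c1, c2),
      nn_conv_op(c2, c2), sv("s2"), pool,
      nn_conv_op(c2, c2),
      nn_conv_op(c2, c2), up, cc("s2"),
      nn_conv_op(2 * c2, c2),
      nn_conv_op(c2, c1), up, cc("s1"),
      nn_conv_op(2 * c1, c1),
      nn_conv_op(c1, 1, act = "linear")
    ))
}

#' Build an untrained reconstruction network
#'
#' Instantiates the layers of a [model_spec()] with seeded Gaussian
#' (He-style) weight initialisation.  The odd input length is padded to a
#' multiple of 4 by edge replication inside the model and cropped back at
#' the output, so pooling twice is exact and invisible at the interface.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialisation.
#' @return a `cest_model` object (untrained).
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  ops <- with_seed(seed, build_ops(spec))
  n <- spec$input_length
  pad_total <- (4 - n %% 4) %% 4
  structure(list(spec = spec, ops = ops, seed = as.integer(seed),
                 pad_left = pad_total %/% 2,
                 pad_right = pad_total - pad_total %/% 2,
                 trained = FALSE, history = NULL),
            class = "cest_model")
}

#' Count the layers of a model by introspection
#'
#' @param model a `cest_model` (or `model_spec`).
#' @return list with counts `conv`, `pool`, `upsample`, `skip`.
#' @export
layer_counts <- function(model) {
  ops <- if (inherits(model, "cest_model")) model$ops else build_ops(model)
  types <- vapply(ops, `[[`, character(1), "type")
  list(conv = sum(types == "conv"),
       pool = sum(types == "pool"),
       upsample = sum(types == "up"),
       skip = sum(types == "concat"))
}

#' @export
print.cest_model <- function(x, ...) {
  lc <- layer_counts(x)
  cat(sprintf("<cest_model> %s (%d conv, %d pool, %d upsample, %d skip), input length %d%s\n",
              x$spec$architecture, lc$conv, lc$pool, lc$upsample, lc$skip,
              x$spec$input_length,
              if (x$trained) sprintf("; trained %d epochs", nrow(x$history)) else "; untrained"))
  invisible(x)
}

#' Zero-masked sparse encoding of dense spectra
#'
#' Builds the network input: a length-`N` vector whose sampled positions
#' carry the dense values and whose unsampled positions are zero.  With
#' `mask_channel = TRUE` a second channel carrying the 0/1 sampling mask is
#' appended.
#'
#' @param dense a [zspectrum()], [zspectra()] table, numeric vector, or
#'   matrix (rows = spectra).
#' @param subset an [offset_subset()] with at least 4 offsets.
#' @param mask_channel append the sampling mask as a second channel?
#' @return numeric matrix `(n, N)`, or a 3D array `(n, N, 2)` when
#'   `mask_channel` is set.
#' @export
encode_sparse <- function(dense, subset, mask_channel = FALSE) {
  stopifnot(inherits(subset, "offset_subset"))
  if (length(subset$indices) < 4) stop("subset must have at least 4 offsets")
  vals <- if (inherits(dense, "zspectrum")) rbind(dense$values)
          else if (inherits(dense, "zspectra")) zs_values(dense)
          else rbind(dense)
  if (max(subset$indices) > ncol(vals)) stop("subset exceeds spectrum length")
  out <- matrix(0, nrow(vals), ncol(vals))
  out[, subset$indices] <- vals[, subset$indices]
  if (!mask_channel) return(out)
  m <- matrix(0, nrow(vals), ncol(vals))
  m[, subset$indices] <- 1
  arr <- array(0, c(nrow(vals), ncol(vals), 2))
  arr[, , 1] <- out
  arr[, , 2] <- m
  arr
}
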