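#' Training configuration for the reconstruction networks
#'
#' Mirrors the standard recipe for these models: Adam optimiser, mean
#' absolute error loss, an 80/20 train/validation split, and a callback
#' that halves the learning rate when the validation loss stops improving,
#' never below the floor of 1e-6.
#'
#' @param epochs training epochs (the reference recipe uses 250-500;
#'   smaller values are accepted for scaled-down runs).
#' @param batch_size minibatch size (reference range 5-25).
#' @param validation_split fraction of pairs held out for validation
#'   (default 0.2).
#' @param lr initial Adam learning rate.
#' @param lr_factor multiplicative decay applied on plateau.
#' @param lr_patience epochs without validation improvement before decay.
#' @param min_lr learning-rate floor (1e-6).
#' @param seed integer seed controlling the split and shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 300, batch_size = 16,
                         validation_split = 0.2, lr = 1e-3,
                         lr_factor = 0.5, lr_patience = 10, min_lr = 1e-6,
                         seed = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, validation_split >= 0,
            validation_split < 1, lr > 0, lr_factor > 0, lr_factor <= 1,
            lr_patience >= 1, min_lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 validation_split = validation_split,
                 lr = lr, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience), min_lr = min_lr,
                 seed = as.integer(seed)),
            class = "train_config")
}

as_input_array <- function(x, spec) {
  if (is.array(x) && length(dim(x)) == 3) {
    if (dim(x)[3] != spec$in_channels) stop("input channel mismatch")
    if (dim(x)[2] != spec$input_length) {
      stop(sprintf("input length %d does not match the model's input_length %d",
                   dim(x)[2], spec$input_length))
    }
    return(x)
  }
  x <- rbind(x)
  if (spec$in_channels != 1) stop("model expects a mask channel; pass a 3D array")
  if (ncol(x) != spec$input_length) {
    stop(sprintf("input length %d does not match the model's input_length %d",
                 ncol(x), spec$input_length))
  }
  array(x, c(nrow(x), ncol(x), 1))
}

model_forward_batch <- function(model, X) {
  Xp <- pad_batch(X, model$pad_left, model$pad_right)
  res <- nn_forward(model$ops, Xp)
  n <- model$spec$input_length
  list(pred = res$Y[, model$pad_left + seq_len(n), 1],
       caches = res$caches, full_len = dim(Xp)[2])
}

#' Train a reconstruction network
#'
#' Supervised training of a [build_model()] network on (sparse masked
#' input, dense target) pairs with Adam, mean-absolute-error loss, and a
#' reduce-on-plateau learning-rate schedule monitored on the validation
#' loss.  Training aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model an untrained (or previously trained) `cest_model`.
#' @param x inputs: matrix `(n, N)` of zero-masked spectra (or 3D array
#'   with a mask channel); at least 5 rows.
#' @param y targets: matrix `(n, N)` of dense spectra.
#' @param config a [train_config()].
#' @return the trained `cest_model`; `$history` is a data frame with one
#'   row per epoch (`epoch`, `lr`, `train_loss`, `val_loss`).
#' @export
train_model <- function(model, x, y, config = train_config()) {
  stopifnot(inherits(model, "cest_model"), inherits(config, "train_config"))
  X <- as_input_array(x, model$spec)
  Y <- rbind(y)
  n <- dim(X)[1]
  if (n < 5) stop("need at least 5 training pairs")
  if (nrow(Y) != n || ncol(Y) != model$spec$input_length) {
    stop("`y` must be (n, input_length)")
  }
  n_len <- model$spec$input_length

  with_seed(config$seed, {
    perm <- sample.int(n)
    n_val <- floor(config$validation_split * n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)

    ops <- model$ops
    state <- adam_init(ops)
    lr <- config$lr
    step <- 0L
    best_monitor <- Inf
    wait <- 0L
    hist <- vector("list", config$epochs)

    Xval <- X[val_idx, , , drop = FALSE]
    Yval <- Y[val_idx, , drop = FALSE]

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      batch_losses <- numeric(0)
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
        Xb <- X[idx, , , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        model$ops <- ops
        fw <- model_forward_batch(model, Xb)
        err <- fw$pred - Yb
        loss <- mean(abs(err))
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d; try a lower learning rate",
                       epoch))
        }
        batch_losses <- c(batch_losses, loss)
        # d(mean|err|)/dpred, embedded into the padded length-channel array
        dpred <- sign(err) / length(err)
        dY <- array(0, c(length(idx), fw$full_len, 1))
        dY[, model$pad_left + seq_len(n_len), 1] <- dpred
        bw <- nn_backward(ops, fw$caches, dY)
        step <- step + 1L
        upd <- adam_step(ops, bw$grads, state, lr, step)
        ops <- upd$ops
        state <- upd$state
      }
      model$ops <- ops
      train_loss <- mean(batch_losses)
      val_loss <- if (length(val_idx) > 0) {
        mean(abs(model_forward_batch(model, Xval)$pred - Yval))
      } else NA_real_
      monitor <- if (is.na(val_loss)) train_loss else val_loss
      if (monitor < best_monitor - 1e-8) {
        best_monitor <- monitor
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$lr_patience && lr > config$min_lr) {
          lr <- max(lr * config$lr_factor, config$min_lr)
          wait <- 0L
        }
      }
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  train_loss = train_loss,
                                  val_loss = val_loss)
    }

    model$history <- do.call(rbind, hist)
    model$trained <- TRUE
    model$train_config <- config
    model$n_train <- length(tr_idx)
    model$n_val <- length(val_idx)
    model
  })
}

#' Predict dense Z-spectra from sparse masked inputs
#'
#' @param object a trained `cest_model`.
#' @param newdata matrix `(n, N)` of zero-masked spectra, a single numeric
#'   vector, or a 3D array with mask channel.
#' @param clip clip predictions to the physical range `[0, 1.05]`?
#' @param ... unused.
#' @return numeric matrix `(n, N)` of reconstructed dense spectra.
#' @export
predict.cest_model <- function(object, newdata, clip = FALSE, ...) {
  X <- as_input_array(newdata, object$spec)
  pred <- model_forward_batch(object, X)$pred
  pred <- rbind(pred)
  if (!all(is.finite(pred))) stop("model produced non-finite predictions")
  if (clip) pred <- pmin(pmax(pred, 0), 1.05)
  pred
}
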