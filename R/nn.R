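# Minimal 1D convolutional network engine (internal).
#
# Activations are 3D arrays (batch, length, channels).  A kernel-3 "same"
# convolution is computed as three shifted matrix products, which keeps the
# whole forward/backward pass in BLAS calls.  Supported ops: conv (ReLU or
# linear), max-pool size 2, nearest-neighbour upsample x2, and named
# save/concat pairs implementing U-Net skip connections.

shift_prev <- function(X) {
  L <- dim(X)[2]
  Xs <- array(0, dim(X))
  Xs[, 2:L, ] <- X[, 1:(L - 1), , drop = FALSE]
  Xs
}

shift_next <- function(X) {
  L <- dim(X)[2]
  Xs <- array(0, dim(X))
  Xs[, 1:(L - 1), ] <- X[, 2:L, , drop = FALSE]
  Xs
}

flat <- function(X) {
  d <- dim(X)
  dim(X) <- c(d[1] * d[2], d[3])
  X
}

unflat <- function(M, B, L) {
  dim(M) <- c(B, L, ncol(M))
  M
}

nn_conv_op <- function(cin, cout, act = c("relu", "linear")) {
  act <- match.arg(act)
  sd <- if (act == "relu") sqrt(2 / (3 * cin)) else sqrt(1 / (3 * cin))
  W <- lapply(1:3, function(i) matrix(rnorm(cin * cout, 0, sd), cin, cout))
  list(type = "conv", W = W, b = numeric(cout), act = act,
       cin = cin, cout = cout)
}

conv_forward <- function(X, op) {
  d <- dim(X)
  Xpf <- flat(shift_prev(X))
  Xf <- flat(X)
  Xnf <- flat(shift_next(X))
  Zf <- Xpf %*% op$W[[1]] + Xf %*% op$W[[2]] + Xnf %*% op$W[[3]]
  Zf <- sweep(Zf, 2, op$b, "+")
  if (op$act == "relu") {
    mask <- Zf > 0
    Yf <- Zf * mask
    list(Y = unflat(Yf, d[1], d[2]),
         cache = list(Xpf = Xpf, Xf = Xf, Xnf = Xnf, mask = mask,
                      B = d[1], L = d[2]))
  } else {
    list(Y = unflat(Zf, d[1], d[2]),
         cache = list(Xpf = Xpf, Xf = Xf, Xnf = Xnf, mask = NULL,
                      B = d[1], L = d[2]))
  }
}

conv_backward <- function(dY, op, cache) {
  B <- cache$B; L <- cache$L
  dYf <- flat(dY)
  if (!is.null(cache$mask)) dYf <- dYf * cache$mask
  g <- list(W = list(crossprod(cache$Xpf, dYf),
                     crossprod(cache$Xf, dYf),
                     crossprod(cache$Xnf, dYf)),
            b = colSums(dYf))
  A1 <- unflat(tcrossprod(dYf, op$W[[1]]), B, L)
  A2 <- unflat(tcrossprod(dYf, op$W[[2]]), B, L)
  A3 <- unflat(tcrossprod(dYf, op$W[[3]]), B, L)
  list(dX = shift_next(A1) + A2 + shift_prev(A3), g = g)
}

pool_forward <- function(X) {
  L <- dim(X)[2]
  odd <- seq(1, L, by = 2)
  X1 <- X[, odd, , drop = FALSE]
  X2 <- X[, odd + 1, , drop = FALSE]
  mask <- X1 >= X2
  list(Y = X1 * mask + X2 * !mask, cache = list(mask = mask, L = L))
}

pool_backward <- function(dY, cache) {
  d <- dim(dY)
  dX <- array(0, c(d[1], cache$L, d[3]))
  odd <- seq(1, cache$L, by = 2)
  dX[, odd, ] <- dY * cache$mask
  dX[, odd + 1, ] <- dY * !cache$mask
  dX
}

up_forward <- function(X) {
  d <- dim(X)
  Y <- array(0, c(d[1], 2 * d[2], d[3]))
  odd <- seq(1, 2 * d[2], by = 2)
  Y[, odd, ] <- X
  Y[, odd + 1, ] <- X
  Y
}

up_backward <- function(dY) {
  L2 <- dim(dY)[2]
  odd <- seq(1, L2, by = 2)
  dY[, odd, , drop = FALSE] + dY[, odd + 1, , drop = FALSE]
}

concat_channels <- function(X, S) {
  d <- dim(X)
  stopifnot(all(dim(S)[1:2] == d[1:2]))
  Y <- array(0, c(d[1], d[2], d[3] + dim(S)[3]))
  Y[, , seq_len(d[3])] <- X
  Y[, , d[3] + seq_len(dim(S)[3])] <- S
  Y
}

nn_forward <- function(ops, X) {
  saves <- list()
  caches <- vector("list", length(ops))
  for (t in seq_along(ops)) {
    op <- ops[[t]]
    if (op$type == "conv") {
      res <- conv_forward(X, op)
      X <- res$Y
      caches[[t]] <- res$cache
    } else if (op$type == "pool") {
      res <- pool_forward(X)
      X <- res$Y
      caches[[t]] <- res$cache
    } else if (op$type == "up") {
      X <- up_forward(X)
    } else if (op$type == "save") {
      saves[[op$name]] <- X
    } else if (op$type == "concat") {
      caches[[t]] <- dim(X)[3]
      X <- concat_channels(X, saves[[op$name]])
    } else {
      stop("unknown op type: ", op$type)
    }
  }
  list(Y = X, caches = caches)
}

nn_backward <- function(ops, caches, dY) {
  grads <- vector("list", length(ops))
  skip <- list()
  for (t in rev(seq_along(ops))) {
    op <- ops[[t]]
    if (op$type == "conv") {
      res <- conv_backward(dY, op, caches[[t]])
      dY <- res$dX
      grads[[t]] <- res$g
    } else if (op$type == "pool") {
      dY <- pool_backward(dY, caches[[t]])
    } else if (op$type == "up") {
      dY <- up_backward(dY)
    } else if (op$type == "concat") {
      c1 <- caches[[t]]
      ctot <- dim(dY)[3]
      dS <- dY[, , (c1 + 1):ctot, drop = FALSE]
      skip[[op$name]] <- if (is.null(skip[[op$name]])) dS else skip[[op$name]] + dS
      dY <- dY[, , seq_len(c1), drop = FALSE]
    } else if (op$type == "save") {
      if (!is.null(skip[[op$name]])) dY <- dY + skip[[op$name]]
    }
  }
  list(dX = dY, grads = grads)
}

adam_init <- function(ops) {
  lapply(ops, function(op) {
    if (op$type != "conv") return(NULL)
    list(mW = lapply(op$W, function(w) w * 0),
         vW = lapply(op$W, function(w) w * 0),
         mb = op$b * 0, vb = op$b * 0)
  })
}

adam_step <- function(ops, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(ops)) {
    if (ops[[i]]$type != "conv") next
    g <- grads[[i]]
    st <- state[[i]]
    for (j in 1:3) {
      st$mW[[j]] <- beta1 * st$mW[[j]] + (1 - beta1) * g$W[[j]]
      st$vW[[j]] <- beta2 * st$vW[[j]] + (1 - beta2) * g$W[[j]]^2
      ops[[i]]$W[[j]] <- ops[[i]]$W[[j]] -
        lr * (st$mW[[j]] / bc1) / (sqrt(st$vW[[j]] / bc2) + eps)
    }
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    ops[[i]]$b <- ops[[i]]$b - lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    state[[i]] <- st
  }
  list(ops = ops, state = state)
}

# pad a (B, n, C) batch along length to a multiple of 4 by edge replication
pad_batch <- function(X, pad_left, pad_right) {
  if (pad_left + pad_right == 0) return(X)
  d <- dim(X)
  Y <- array(0, c(d[1], d[2] + pad_left + pad_right, d[3]))
  Y[, pad_left + seq_len(d[2]), ] <- X
  if (pad_left > 0) for (i in seq_len(pad_left)) Y[, i, ] <- X[, 1, ]
  if (pad_right > 0) {
    for (i in seq_len(pad_right)) Y[, pad_left + d[2] + i, ] <- X[, d[2], ]
  }
  Y
}
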