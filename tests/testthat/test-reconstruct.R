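test_that("sparse encoding zero-fills unsampled offsets", {
  g <- grid101()
  sp <- simulate_zspectrum(g)
  full <- offset_subset(1:101, g)
  expect_equal(encode_sparse(sp, full)[1, ], sp$values)

  sub <- prng_select(g, 10, seed = 1)
  x <- encode_sparse(sp, sub)
  expect_equal(sum(x == 0), 91)
  expect_equal(x[1, sub$indices], sp$values[sub$indices])

  expect_error(encode_sparse(sp, offset_subset(c(1, 2, 3), g)), "at least 4")

  xm <- encode_sparse(sp, sub, mask_channel = TRUE)
  expect_equal(dim(xm), c(1, 101, 2))
  expect_equal(sum(xm[1, , 2]), 10)
})

test_that("architectures have the documented layer structure", {
  counts <- list(
    autoencoder = list(conv = 6, pool = 2, upsample = 2, skip = 0),
    unet1 = list(conv = 6, pool = 2, upsample = 2, skip = 2),
    unet2 = list(conv = 10, pool = 2, upsample = 2, skip = 2)
  )
  for (arch in names(counts)) {
    m <- build_model(model_spec(arch, channels = c(4, 8)), seed = 1)
    lc <- layer_counts(m)
    expect_equal(lc$conv, counts[[arch]]$conv, label = arch)
    expect_equal(lc$pool, counts[[arch]]$pool)
    expect_equal(lc$upsample, counts[[arch]]$upsample)
    expect_equal(lc$skip, counts[[arch]]$skip)
    if (arch == "unet1") expect_gte(lc$skip, 1)

    # forward pass on zero input: finite, length 101
    out <- predict(m, matrix(0, 1, 101))
    expect_equal(dim(out), c(1, 101))
    expect_true(all(is.finite(out)))
  }
  expect_error(model_spec("resnet"), "'arg'")
  # weight init is seed-reproducible
  m1 <- build_model(model_spec("unet1", channels = c(4, 8)), seed = 9)
  m2 <- build_model(model_spec("unet1", channels = c(4, 8)), seed = 9)
  expect_identical(m1$ops, m2$ops)
})

test_that("backpropagated gradients match numerical differentiation", {
  for (arch in c("autoencoder", "unet2")) {
    m <- build_model(model_spec(arch, input_length = 16, channels = c(3, 4)),
                     seed = 7)
    withr::with_seed(1, {
      X <- array(rnorm(2 * 16), c(2, 16, 1))
      Yt <- matrix(rnorm(2 * 16), 2, 16)
    })
    fw <- zspeed:::model_forward_batch(m, X)
    dpred <- sign(fw$pred - Yt) / length(Yt)
    dY <- array(0, c(2, fw$full_len, 1))
    dY[, m$pad_left + 1:16, 1] <- dpred
    grads <- zspeed:::nn_backward(m$ops, fw$caches, dY)$grads
    loss_of <- function(mm) mean(abs(zspeed:::model_forward_batch(mm, X)$pred - Yt))
    eps <- 1e-6
    withr::with_seed(2, {
      for (i in seq_along(m$ops)) {
        if (m$ops[[i]]$type != "conv") next
        j <- sample(3, 1)
        r <- sample(length(m$ops[[i]]$W[[j]]), 1)
        mp <- m; mp$ops[[i]]$W[[j]][r] <- mp$ops[[i]]$W[[j]][r] + eps
        mm <- m; mm$ops[[i]]$W[[j]][r] <- mm$ops[[i]]$W[[j]][r] - eps
        num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
        expect_equal(grads[[i]]$W[[j]][r], num, tolerance = 1e-4)
      }
    })
  }
})

test_that("training splits pairs 80/20, respects the lr floor, and learns", {
  g <- grid101()
  corpus <- synthetic_corpus(100, g, seed = 50)
  sub <- prng_select(g, 20, seed = 1)
  m <- build_model(model_spec("autoencoder", channels = c(8, 16)), seed = 3)
  cfg <- train_config(epochs = 30, batch_size = 16, lr_patience = 3, seed = 4)
  fit <- train_model(m, encode_sparse(corpus, sub), corpus, cfg)

  expect_equal(fit$n_train, 80)
  expect_equal(fit$n_val, 20)
  expect_equal(nrow(fit$history), 30)
  expect_true(all(fit$history$lr >= 1e-6))
  # validation loss improves over training
  expect_lt(tail(fit$history$val_loss, 1), fit$history$val_loss[1])

  # deterministic retrain: identical history
  fit2 <- train_model(m, encode_sparse(corpus, sub), corpus, cfg)
  expect_equal(fit$history$train_loss, fit2$history$train_loss, tolerance = 1e-12)

  # prediction contract
  pred <- predict(fit, encode_sparse(corpus[1:5, ], sub))
  expect_equal(dim(pred), c(5, 101))
  clipped <- predict(fit, encode_sparse(corpus[1:5, ], sub), clip = TRUE)
  expect_true(all(clipped >= 0 & clipped <= 1.05))

  expect_error(train_model(m, encode_sparse(corpus[1:3, ], sub),
                           corpus[1:3, ], cfg), "at least 5")
  expect_error(predict(fit, matrix(0, 2, 50)), "input_length|dim|non-conformable")
})

test_that("a model memorizes a single repeated training pair", {
  g <- grid101()
  dense <- simulate_zspectrum(g)$values
  sub <- prng_select(g, 10, seed = 3)
  x1 <- encode_sparse(dense, sub)
  m <- build_model(model_spec("autoencoder", channels = c(8, 16)), seed = 11)
  fit <- train_model(m, x1[rep(1, 25), , drop = FALSE],
                     matrix(dense, 25, 101, byrow = TRUE),
                     train_config(epochs = 400, batch_size = 5, seed = 5))
  expect_lt(mean(abs(predict(fit, x1) - dense)), 0.005)
})
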