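# Small geometries keep the compiled engine checks fast; the full
# 184 x 5 geometry is exercised by the parameter-count and end-to-end
# distillation tests.

tiny_model <- function(seed = 42) {
  m <- build_surrogate(input_h = 8, input_w = 5, conv1_maps = 3,
                       conv2_maps = 4, hidden = 6, seed = seed)
  # move biases off zero so no ReLU pre-activation sits exactly on its
  # kink (padding-only patches otherwise do, where one-sided derivatives
  # differ)
  m$params$b1 <- m$params$b1 + 0.07
  m$params$b2 <- m$params$b2 - 0.03
  m$params$bd <- m$params$bd + 0.05
  m
}

test_that("surrogate construction is seeded and well-formed", {
  a <- build_surrogate(seed = 3)
  b <- build_surrogate(seed = 3)
  expect_identical(a$params, b$params)
  x0 <- array(0, c(184, 5, 1))
  expect_true(is.finite(predict(a, x0)))
  expect_identical(predict(a, x0), predict(b, x0))
  expect_false(identical(a$params$W1, build_surrogate(seed = 4)$params$W1))
})

test_that("parameter count matches the layer-by-layer arithmetic", {
  m <- build_surrogate()   # 184 x 5, 3x3 kernels, pad 2, 32/64 maps, 64 dense
  # conv feature maps grow by 2 rows/cols per layer: 186x7 then 188x9
  flat <- 188 * 9 * 64
  expect_equal(
    n_parameters(m),
    (9 * 32 + 32) + (32 * 9 * 64 + 64) + (flat * 64 + 64) + (64 + 1))
})

test_that("the compiled forward pass matches a double-precision R oracle", {
  m <- tiny_model()
  set.seed(5)
  X <- array(rnorm(8 * 5 * 4), c(8, 5, 4))
  got <- predict(m, X)
  want <- vapply(1:4, function(i)
    oracle_cnn_forward(m$params, m$dims, X[, , i]), numeric(1))
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("compiled parameter gradients match finite differences of the oracle", {
  m <- tiny_model()
  set.seed(6)
  X <- array(rnorm(8 * 5 * 3), c(8, 5, 3))
  y <- rnorm(3)
  out <- cnn_loss_grad_cpp(m$params, X, y, m$dims)
  loss_oracle <- function(params) {
    pr <- vapply(1:3, function(i)
      oracle_cnn_forward(params, m$dims, X[, , i]), numeric(1))
    mean((pr - y)^2)
  }
  set.seed(7)
  for (k in names(out$grads)) {
    for (idx in sample(length(out$grads[[k]]), min(4, length(out$grads[[k]])))) {
      h <- 1e-5
      p1 <- m$params; p1[[k]][idx] <- p1[[k]][idx] + h
      p2 <- m$params; p2[[k]][idx] <- p2[[k]][idx] - h
      fd <- (loss_oracle(p1) - loss_oracle(p2)) / (2 * h)
      expect_equal(out$grads[[k]][idx], fd, tolerance = 2e-3,
                   label = sprintf("grad %s[%d]", k, idx))
    }
  }
})

test_that("a high-capacity net overfits ten samples to near-zero error", {
  set.seed(11)
  X <- array(rnorm(184 * 5 * 10, 0, 1), c(184, 5, 10))
  y <- rnorm(10, 500, 100)
  m <- build_surrogate(conv1_maps = 4, conv2_maps = 8, hidden = 32, seed = 3)
  fit <- train_surrogate(m, X, y, X, y,
                         config = train_config(lr = 1e-2, batch_size = 10,
                                               max_epochs = 400,
                                               patience = 400, seed = 3))
  train_mse <- fit$history$train_mse[nrow(fit$history)]
  expect_lt(train_mse, 1e-3 * var(y))
})

test_that("constant targets are learned as a constant", {
  set.seed(12)
  X <- array(rnorm(184 * 5 * 12), c(184, 5, 12))
  y <- rep(400, 12)
  m <- build_surrogate(conv1_maps = 2, conv2_maps = 4, hidden = 8, seed = 1)
  fit <- train_surrogate(m, X[, , 1:8], y[1:8], X[, , 9:12], y[9:12],
                         config = train_config(batch_size = 8,
                                               max_epochs = 30, seed = 1))
  pr <- predict(fit, X[, , 9:12])
  expect_equal(pr, rep(400, 4), tolerance = 0.05)
  expect_lt(fit$val_mse_best, 1)
})

test_that("early stopping halts exactly patience epochs past the best", {
  set.seed(13)
  X <- array(rnorm(184 * 5 * 8), c(184, 5, 8))
  y <- rnorm(8, 100, 10)
  m <- build_surrogate(conv1_maps = 2, conv2_maps = 2, hidden = 4, seed = 1)
  # a vanishing learning rate freezes the weights, so the validation
  # loss ties every epoch; ties are non-improvements
  fit <- train_surrogate(m, X[, , 1:6], y[1:6], X[, , 7:8], y[7:8],
                         config = train_config(lr = 1e-30, batch_size = 6,
                                               max_epochs = 100,
                                               patience = 10, seed = 1))
  expect_identical(fit$best_epoch, 1L)
  expect_identical(nrow(fit$history), 11L)
})

test_that("prediction is empty-safe, batch-invariant, and shape-checked", {
  m <- build_surrogate(seed = 8)
  expect_identical(predict(m, array(0, c(184, 5, 0))), numeric(0))
  set.seed(14)
  X <- array(rnorm(184 * 5 * 7), c(184, 5, 7))
  together <- predict(m, X)
  alone <- vapply(1:7, function(i) predict(m, X[, , i]), numeric(1))
  expect_equal(together, alone, tolerance = 1e-5)
  expect_error(predict(m, array(0, c(10, 5, 1))), "shape")
})

test_that("stored best validation loss is reproduced by prediction", {
  set.seed(15)
  X <- array(rnorm(184 * 5 * 20), c(184, 5, 20))
  y <- 300 + 50 * apply(X[1:10, 1, ], 2, mean) + rnorm(20, 0, 1)
  m <- build_surrogate(conv1_maps = 2, conv2_maps = 4, hidden = 8, seed = 3)
  fit <- train_surrogate(m, X[, , 1:15], y[1:15], X[, , 16:20], y[16:20],
                         config = train_config(batch_size = 5,
                                               max_epochs = 15, seed = 3))
  pr <- predict(fit, X[, , 16:20])
  expect_equal(mean((pr - y[16:20])^2), fit$val_mse_best,
               tolerance = 1e-6)
})

test_that("training history is deterministic for a fixed seed", {
  set.seed(16)
  X <- array(rnorm(184 * 5 * 10), c(184, 5, 10))
  y <- rnorm(10, 200, 30)
  run <- function() {
    m <- build_surrogate(conv1_maps = 2, conv2_maps = 2, hidden = 4, seed = 5)
    train_surrogate(m, X[, , 1:8], y[1:8], X[, , 9:10], y[9:10],
                    config = train_config(batch_size = 4, max_epochs = 5,
                                          seed = 5))$history
  }
  expect_identical(run(), run())
})
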