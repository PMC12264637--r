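test_that("initialization is reproducible with the documented shapes and bounds", {
  m1 <- init_mlp(c(15, 30, 20, 1), seed = 3)
  m2 <- init_mlp(c(15, 30, 20, 1), seed = 3)
  expect_identical(m1, m2)
  expect_equal(dim(m1$weights[[1]]), c(30, 15))
  expect_equal(dim(m1$weights[[2]]), c(20, 30))
  expect_equal(dim(m1$weights[[3]]), c(1, 20))
  expect_identical(m1$activations, c("tansig", "tansig", "linear"))
  for (l in 1:3) {
    expect_lte(max(abs(m1$weights[[l]])), 1 / sqrt(ncol(m1$weights[[l]])))
    expect_true(all(m1$biases[[l]] == 0))
  }
  expect_equal(n_params(m1), 30 * 15 + 30 + 20 * 30 + 20 + 20 + 1)
  expect_error(init_mlp(c(15)), "at least")
})

test_that("forward propagation reproduces hand-computed activations", {
  ident <- init_mlp(c(1, 1), seed = 1)
  ident$weights[[1]][] <- 1
  ident$activations <- "linear"
  expect_equal(as.numeric(forward_mlp(ident, 3.5)$a[[2]]), 3.5)

  net <- init_mlp(c(2, 2, 1), seed = 1)
  net$weights[[1]][] <- 0.5
  net$weights[[2]][] <- 0.5
  out <- forward_mlp(net, c(1, 1))
  expect_equal(as.numeric(out$a[[2]]), rep(tanh(1), 2))
  expect_equal(as.numeric(out$a[[3]]), 0.5 * (tanh(1) + tanh(1)))

  zero <- init_mlp(c(3, 4, 1), seed = 1)
  for (l in seq_along(zero$weights)) zero$weights[[l]][] <- 0
  expect_equal(as.numeric(forward_mlp(zero, c(1, 2, 3))$a[[2]]), rep(0, 4))
  expect_error(forward_mlp(net, c(1, 2, 3)), "expects")
})

test_that("mean squared error follows its definition", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(c(1, 2), c(2, 2)), 0.5)
  expect_equal(mse_loss(c(1, 2, 5), c(0, 1, 9)), mse_loss(c(5, 1, 2), c(9, 0, 1)))
  expect_error(mse_loss(1:3, 1:2), "equal")
})

test_that("backpropagation matches finite differences and the scalar closed form", {
  model <- init_mlp(c(4, 6, 3, 1), seed = 8)
  set.seed(9)
  x <- matrix(rnorm(4 * 8), 4, 8)
  y <- matrix(rnorm(8), 1, 8)
  cache <- forward_mlp(model, x)
  grads <- backward_mlp(model, cache, y)
  h <- 1e-6
  for (l in seq_along(model$weights)) {
    idx <- cbind(sample(nrow(model$weights[[l]]), 4, replace = TRUE),
                 sample(ncol(model$weights[[l]]), 4, replace = TRUE))
    for (k in seq_len(nrow(idx))) {
      mp <- model; mp$weights[[l]][idx[k, 1], idx[k, 2]] <-
        mp$weights[[l]][idx[k, 1], idx[k, 2]] + h
      mm <- model; mm$weights[[l]][idx[k, 1], idx[k, 2]] <-
        mm$weights[[l]][idx[k, 1], idx[k, 2]] - h
      num <- (mse_loss(y, forward_mlp(mp, x)$a[[4]]) -
                mse_loss(y, forward_mlp(mm, x)$a[[4]])) / (2 * h)
      ana <- grads$dW[[l]][idx[k, 1], idx[k, 2]]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-6), 1e-5)
    }
  }

  # single linear neuron: dLoss/dw = 2 (w x - y) x exactly
  lin <- init_mlp(c(1, 1), seed = 1)
  lin$weights[[1]][] <- 0.7
  cache <- forward_mlp(lin, 1.3)
  g <- backward_mlp(lin, cache, 2.0)
  expect_equal(as.numeric(g$dW[[1]]), 2 * (0.7 * 1.3 - 2.0) * 1.3)

  expect_error(backward_mlp(lin, cache, c(1, 2)), "shape")
})

test_that("the gradient step applies the update rule and nothing else", {
  model <- init_mlp(c(2, 3, 1), seed = 2)
  cache <- forward_mlp(model, c(0.3, -0.2))
  grads <- backward_mlp(model, cache, 1.5)
  expect_identical(gd_step(model, grads, 0), model)

  stepped <- gd_step(model, grads, 0.1)
  expect_equal(stepped$weights[[1]], model$weights[[1]] - 0.1 * grads$dW[[1]])
  # two half-steps on fixed gradients equal one full step
  twice <- gd_step(gd_step(model, grads, 0.05), grads, 0.05)
  expect_equal(twice$weights[[2]], stepped$weights[[2]])

  bad <- grads; bad$dW[[2]][1, 1] <- Inf
  expect_error(gd_step(model, bad, 0.1), "layer 2")

  # scalar hand arithmetic: w = 1, grad = 2, eta = 0.1 -> 0.8
  lin <- init_mlp(c(1, 1), seed = 1); lin$weights[[1]][] <- 1
  g <- list(dW = list(matrix(2)), db = list(0))
  expect_equal(as.numeric(gd_step(lin, g, 0.1)$weights[[1]]), 0.8)
})

test_that("training separates two Gaussian clouds and is deterministic", {
  set.seed(11)
  n <- 200
  x <- rbind(matrix(rnorm(n, mean = -2, sd = 0.5), n / 2, 2),
             matrix(rnorm(n, mean = 2, sd = 0.5), n / 2, 2))
  y <- rep(c(1, 2), each = n / 2)
  fit <- train_mlp(init_mlp(c(2, 8, 1), seed = 11), x, y,
                   config = training_config(max_epochs = 2000))
  pred <- predict_mlp(fit$model, x)
  expect_gte(mean((pred$score >= 1.5) + 1 == y), 0.95)
  expect_lte(tail(fit$history$train_mse, 1), fit$history$train_mse[1])

  fit2 <- train_mlp(init_mlp(c(2, 8, 1), seed = 11), x, y,
                    config = training_config(max_epochs = 2000))
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$weights, fit2$model$weights)
})

test_that("zero-epoch training is a no-op and empty training sets refuse", {
  model <- init_mlp(c(2, 4, 1), seed = 1)
  fit <- train_mlp(model, matrix(rnorm(10), 5, 2), rep(c(1, 2), c(2, 3)),
                   config = training_config(max_epochs = 0))
  expect_identical(fit$model, model)
  expect_equal(nrow(fit$history), 0)
  expect_error(train_mlp(model, matrix(numeric(0), 0, 2), numeric(0)),
               "empty")
})

test_that("divergent training raises an informative error", {
  set.seed(4)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c(1, 2), 10)
  expect_error(
    train_mlp(init_mlp(c(2, 8, 1), seed = 4), x, y,
              config = training_config(eta = 1e8, max_epochs = 50)),
    "diverg|learning rate")
})

test_that("the 1.5 threshold separates labels with ties going unhealthy", {
  model <- init_mlp(c(2, 1), seed = 1)
  model$activations <- "linear"
  model$weights[[1]][] <- 0
  for (b in c(1.8, 1.5, 1.2)) {
    model$biases[[1]] <- b
    out <- predict_mlp(model, matrix(0, 1, 2))
    expect_equal(out$score, b)
    expect_identical(out$label, if (b >= 1.5) "unhealthy" else "healthy")
  }
})

test_that("model checkpoints round trip through JSON", {
  set.seed(15)
  x <- matrix(rnorm(60), 30, 2)
  y <- rep(c(1, 2), 15)
  fit <- train_mlp(init_mlp(c(2, 5, 1), seed = 15), x, y,
                   config = training_config(max_epochs = 200))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, path)
  back <- load_model(path)
  expect_equal(back$weights, fit$model$weights)
  expect_equal(back$standardizer$center, as.numeric(fit$model$standardizer$center))
  expect_equal(back$threshold, 1.5)
  expect_equal(predict_mlp(back, x)$score, predict_mlp(fit$model, x)$score)
})
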