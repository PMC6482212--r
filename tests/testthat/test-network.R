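# Network construction, forward evaluation, analytic input gradients and
# training behaviour.

test_that("layer shapes chain correctly and layer counts are bounded", {
  net <- init_network(72, hidden = c(8, 8, 8), seed = 1)
  expect_equal(lapply(net$weights, dim),
               list(c(72L, 8L), c(8L, 8L), c(8L, 8L), c(8L, 1L)))
  expect_equal(net$layer_sizes, c(72L, 8L, 8L, 8L, 1L))
  expect_true(all(vapply(net$biases, function(b) all(b == 0), logical(1))))
  expect_error(init_network(72, hidden = integer(0)), "1 and 3")
  expect_error(init_network(72, hidden = c(4, 4, 4, 4)), "1 and 3")
  expect_error(init_network(72, hidden = 8, activations = "gelu"), "unknown")
})

test_that("weight initialisation is fan-in bounded and seed-reproducible", {
  n1 <- init_network(30, 16, seed = 9)
  n2 <- init_network(30, 16, seed = 9)
  n3 <- init_network(30, 16, seed = 10)
  expect_identical(n1$weights, n2$weights)
  expect_false(identical(n1$weights, n3$weights))
  lim <- sqrt(6 / 30)
  expect_true(all(abs(n1$weights[[1]]) <= lim))
})

test_that("forward matches hand-computable and collapsed-affine oracles", {
  # zero weights, sigmoid hidden: activations 0.5, zero output weights -> 0
  net <- init_network(4, 3, "sigmoid", seed = 1)
  net$weights <- lapply(net$weights, function(w) w * 0)
  net$biases <- lapply(net$biases, function(b) b * 0)
  expect_equal(forward(net, rep(0, 4)), 0)

  # 1-1-1 sigmoid net, w = 1, b = 0: forward(0) = 0.5 * w_out
  tiny <- init_network(1, 1, "sigmoid", seed = 1)
  tiny$weights <- list(matrix(1), matrix(0.8))
  tiny$biases <- list(0, 0)
  expect_equal(forward(tiny, 0), 0.5 * 0.8, tolerance = 1e-12)

  # all-linear net equals the collapsed affine map
  set.seed(3)
  lin <- init_network(6, c(4, 3), c("linear", "linear"), seed = 3)
  x <- matrix(rnorm(30), 5, 6)
  w <- lin$weights; b <- lin$biases
  collapsed_w <- w[[1]] %*% w[[2]] %*% w[[3]]
  collapsed_b <- (b[[1]] %*% w[[2]] + b[[2]]) %*% w[[3]] + b[[3]]
  expect_equal(forward(lin, x), drop(x %*% collapsed_w) + drop(collapsed_b),
               tolerance = 1e-12)
  expect_error(forward(lin, rep(0, 5)), "expects 6")
})

test_that("analytic input gradients match finite differences and edge cases", {
  # constant Jacobian for all-linear nets
  lin <- init_network(5, 3, "linear", seed = 2)
  g1 <- input_gradient(lin, rnorm(5))
  g2 <- input_gradient(lin, rnorm(5))
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_equal(g1, drop(lin$weights[[1]] %*% lin$weights[[2]]),
               tolerance = 1e-12)

  # zero output-layer weights kill the gradient
  z <- init_network(5, 3, "sigmoid", seed = 2)
  z$weights[[2]] <- z$weights[[2]] * 0
  expect_equal(input_gradient(z, rnorm(5)), rep(0, 5))

  # finite-difference oracle across random architectures and inputs
  for (k in 1:20) {
    net <- random_net(6, seed = 1000 + k)
    x <- with_seed_t(2000 + k, runif(6))
    a <- input_gradient(net, x)
    f <- fd_gradient(net, x)
    expect_lt(max(abs(a - f) / pmax(abs(f), 1e-4)), 1e-4,
              label = sprintf("draw %d", k))
  }
})

test_that("gradient value is independent of batching", {
  net <- random_net(6, seed = 77)
  xs <- matrix(runif(18), 3, 6)
  gm <- input_gradient(net, xs)
  for (i in 1:3) {
    expect_equal(gm[i, ], input_gradient(net, xs[i, ]), tolerance = 1e-12)
  }
})

test_that("an exactly representable linear target is recovered almost perfectly", {
  set.seed(11)
  X <- matrix(runif(300 * 6), 300, 6)
  t_ <- linear_cv(X, w = c(0.8, 0, 0, 0, 0, 0), c = 0.1)
  labels <- split_dataset(300, 0.1, TRUE, seed = 11)
  ts <- scale_targets(t_)
  net <- init_network(6, 4, "linear", seed = 11)
  fit <- train_network(net, X, ts$scaled, labels,
                       training_config(epochs = 400, batch_size = 32,
                                       seed = 11))
  expect_gte(fit$history$pearson_te, 0.999)
})

test_that("full-batch descent on a convex all-linear MSE problem never increases the loss", {
  set.seed(12)
  X <- matrix(runif(100 * 4), 100, 4)
  t_ <- scale_targets(drop(X %*% c(0.3, -0.2, 0.5, 0.1)))$scaled
  net <- init_network(4, 2, "linear", seed = 12)
  fit <- train_network(net, X, t_, labels = NULL,
                       training_config(epochs = 100, batch_size = 100,
                                       optimizer = "sgd", learning_rate = 1e-3,
                                       seed = 12))
  expect_true(all(diff(fit$history$train_loss) <= 1e-12))
})

test_that("zero epochs returns the initial network untouched", {
  net <- init_network(4, 2, seed = 5)
  X <- matrix(runif(40), 10, 4)
  fit <- train_network(net, X, runif(10), NULL,
                       training_config(epochs = 0, seed = 5))
  expect_identical(fit$net$weights, net$weights)
  expect_length(fit$history$train_loss, 0)
})

test_that("training is reproducible and never touches test rows", {
  set.seed(13)
  X <- matrix(runif(80 * 4), 80, 4)
  t_ <- scale_targets(drop(X %*% c(1, -1, 0.5, 0.2)))$scaled
  labels <- split_dataset(80, 0.2, TRUE, seed = 13)
  cfg <- training_config(epochs = 30, batch_size = 16, seed = 13)
  net <- init_network(4, 3, seed = 13)
  f1 <- train_network(net, X, t_, labels, cfg)
  f2 <- train_network(net, X, t_, labels, cfg)
  expect_identical(f1$net$weights, f2$net$weights)
  expect_identical(f1$net$biases, f2$net$biases)
  # perturbing TE targets must not change the trained weights
  t_perturbed <- t_
  t_perturbed[labels == "TE"] <- runif(sum(labels == "TE"))
  f3 <- train_network(net, X, t_perturbed, labels, cfg)
  expect_identical(f1$net$weights, f3$net$weights)
})

test_that("divergence is reported with the epoch index", {
  set.seed(14)
  X <- matrix(runif(50 * 3, 0, 10), 50, 3)
  t_ <- runif(50)
  net <- init_network(3, 3, "linear", seed = 14)
  expect_error(
    train_network(net, X, t_, NULL,
                  training_config(epochs = 50, batch_size = 50,
                                  optimizer = "sgd", learning_rate = 10,
                                  seed = 14)),
    "diverged at epoch")
})

test_that("every optimizer and loss can fit a smooth target", {
  ens <- tiny_cloud()
  X <- fit_and_scale(ens$trajectory, ens$reference)
  ts <- scale_targets(ens$cv_values$values)
  labels <- split_dataset(nrow(X), 0.1, TRUE, seed = 15)
  for (opt in c("adam", "sgd", "rmsprop")) {
    for (loss in c("mean_squared_error", "mean_absolute_error")) {
      net <- init_network(ncol(X), 8, "sigmoid", seed = 15)
      fit <- train_network(net, X, ts$scaled, labels,
                           training_config(epochs = 150, batch_size = 25,
                                           optimizer = opt, loss = loss,
                                           seed = 15))
      expect_gte(fit$history$pearson_tr, 0.3, label = paste(opt, loss))
      expect_lt(fit$history$train_loss[150], fit$history$train_loss[1],
                label = paste(opt, loss))
      expect_length(fit$history$train_loss, 150)
      expect_false(is.na(fit$history$final_test_loss))
    }
  }
})
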