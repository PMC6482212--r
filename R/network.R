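# Feed-forward approximator: 3N inputs (scaled coordinates), 1-3 hidden
# layers, one output in scaled-CV space.  Written directly on matrix algebra
# so the exact same arithmetic can be serialized into PLUMED expressions and
# differentiated analytically with respect to the inputs (the prerequisite
# for using the approximated CV in biased simulations).

ACTIVATIONS <- c("sigmoid", "tanh", "linear", "relu", "softsign", "elu")
OPTIMIZERS  <- c("adam", "sgd", "rmsprop")
LOSSES      <- c("mean_squared_error", "mean_absolute_error")

act_fun <- function(name) {
  switch(name,
    sigmoid  = function(z) 1 / (1 + exp(-z)),
    tanh     = tanh,
    linear   = identity,
    relu     = function(z) pmax(z, 0),
    softsign = function(z) z / (1 + abs(z)),
    elu      = function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1),
    stopf("unknown activation '%s' (supported: %s)", name,
          paste(ACTIVATIONS, collapse = ", ")))
}

# derivative expressed in terms of the pre-activation z
act_deriv <- function(name) {
  switch(name,
    sigmoid  = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) },
    tanh     = function(z) 1 - tanh(z)^2,
    linear   = function(z) rep(1, length(z)),
    relu     = function(z) as.numeric(z > 0),
    softsign = function(z) 1 / (1 + abs(z))^2,
    elu      = function(z) ifelse(z > 0, 1, exp(pmin(z, 0))),
    stopf("unknown activation '%s'", name))
}

#' Initialise a network
#'
#' Builds a fully-connected network with \code{n_inputs} input neurons (three
#' per analysis atom), one to three hidden layers and a single output neuron.
#' Weights are drawn from a seeded symmetric uniform distribution scaled by
#' fan-in, \eqn{U(-\sqrt{6/n_{in}}, +\sqrt{6/n_{in}})}; biases start at zero.
#'
#' @param n_inputs input dimension (3 x atom count).
#' @param hidden integer vector of hidden layer sizes, length 1 to 3.
#' @param activations hidden-layer activation names (recycled), each one of
#'   sigmoid, tanh, linear, relu, softsign, elu.  Default sigmoid.
#' @param seed RNG seed for the weight draw.
#' @param output_activation activation of the output neuron; default linear
#'   (the target CV is min-max scaled separately, see
#'   \code{\link{scale_targets}}).
#' @return An object of class \code{network_spec} with fields
#'   \code{layer_sizes}, \code{activations} (one per hidden layer plus the
#'   output), \code{weights} (list of matrices, inputs x outputs) and
#'   \code{biases}.
#' @examples
#' net <- init_network(72, hidden = c(8, 8, 8), seed = 1)
#' sapply(net$weights, dim)
#' @export
init_network <- function(n_inputs, hidden = 64L, activations = "sigmoid",
                         seed = 1L, output_activation = "linear") {
  if (!is_count(n_inputs) || n_inputs < 1L) stopf("`n_inputs` must be a positive integer")
  hidden <- as.integer(hidden)
  if (length(hidden) < 1L || length(hidden) > 3L) {
    stopf("between 1 and 3 hidden layers are supported (got %d)", length(hidden))
  }
  if (any(hidden < 1L)) stopf("hidden layer sizes must be positive")
  activations <- rep_len(as.character(activations), length(hidden))
  for (a in c(activations, output_activation)) act_fun(a)  # validate names
  sizes <- c(n_inputs, hidden, 1L)
  weights <- vector("list", length(sizes) - 1L)
  biases <- vector("list", length(sizes) - 1L)
  with_seed(seed, {
    for (l in seq_along(weights)) {
      fan_in <- sizes[l]
      lim <- sqrt(6 / fan_in)
      weights[[l]] <- matrix(stats::runif(fan_in * sizes[l + 1L], -lim, lim),
                             nrow = fan_in, ncol = sizes[l + 1L])
      biases[[l]] <- numeric(sizes[l + 1L])
    }
  })
  structure(list(layer_sizes = sizes,
                 activations = c(activations, output_activation),
                 weights = weights,
                 biases = biases),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s; activations %s\n",
              paste(x$layer_sizes, collapse = "-"),
              paste(x$activations, collapse = "/")))
  invisible(x)
}

# forward pass keeping pre-activations (Z) and activations (A) per layer;
# X is a samples x n_inputs matrix.
forward_pass <- function(net, X) {
  a <- X
  zs <- vector("list", length(net$weights))
  as_ <- vector("list", length(net$weights) + 1L)
  as_[[1L]] <- a
  for (l in seq_along(net$weights)) {
    z <- a %*% net$weights[[l]]
    z <- sweep(z, 2L, net$biases[[l]], "+")
    a <- act_fun(net$activations[l])(z)
    zs[[l]] <- z
    as_[[l + 1L]] <- a
  }
  list(z = zs, a = as_)
}

#' Evaluate the network
#'
#' @param net a \code{\link{init_network}} (possibly trained) network.
#' @param x input vector of length \code{layer_sizes[1]}, or a matrix with
#'   one sample per row.
#' @return Scalar output in scaled-CV space (vector for matrix input).
#' @export
forward <- function(net, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != net$layer_sizes[1L]) {
    stopf("input has %d features but the network expects %d",
          ncol(X), net$layer_sizes[1L])
  }
  out <- forward_pass(net, X)$a[[length(net$weights) + 1L]]
  drop(out[, 1L])
}

#' Analytic gradient of the output with respect to the inputs
#'
#' Backpropagates through the activations to give d(output)/d(input), the
#' quantity an MD engine needs to convert a force on the CV into forces on
#' atoms.
#'
#' @inheritParams forward
#' @return Gradient vector of length \code{n_inputs} (matrix, one row per
#'   sample, for matrix input).
#' @export
input_gradient <- function(net, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != net$layer_sizes[1L]) {
    stopf("input has %d features but the network expects %d",
          ncol(X), net$layer_sizes[1L])
  }
  fp <- forward_pass(net, X)
  nl <- length(net$weights)
  # g: d(output)/d(a_l) for each sample (rows)
  g <- matrix(1, nrow = nrow(X), ncol = 1L)
  for (l in nl:1) {
    dz <- act_deriv(net$activations[l])(fp$z[[l]])
    g <- (g * dz) %*% t(net$weights[[l]])
  }
  if (is.matrix(x)) g else drop(g)
}

#' Training configuration
#'
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size (truncated on the final batch).
#' @param optimizer one of adam, sgd, rmsprop.
#' @param loss mean_squared_error or mean_absolute_error.
#' @param seed RNG seed for minibatch shuffling.
#' @param learning_rate step size; default 1e-3 (adam, rmsprop) or 0.01 (sgd).
#' @return An object of class \code{training_config}.
#' @export
training_config <- function(epochs = 1000L, batch_size = 256L,
                            optimizer = "adam", loss = "mean_squared_error",
                            seed = 1L, learning_rate = NULL) {
  if (!is_count(epochs) || epochs < 0L) stopf("`epochs` must be a non-negative integer")
  if (!is_count(batch_size) || batch_size < 1L) stopf("`batch_size` must be positive")
  optimizer <- match.arg(optimizer, OPTIMIZERS)
  loss <- match.arg(loss, LOSSES)
  if (is.null(learning_rate)) {
    learning_rate <- if (optimizer == "sgd") 1e-2 else 1e-3
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 optimizer = optimizer, loss = loss, seed = as.integer(seed),
                 learning_rate = learning_rate),
            class = "training_config")
}

loss_value <- function(loss, pred, target) {
  switch(loss,
         mean_squared_error = mean((pred - target)^2),
         mean_absolute_error = mean(abs(pred - target)))
}

loss_grad <- function(loss, pred, target) {
  m <- length(target)
  switch(loss,
         mean_squared_error = 2 * (pred - target) / m,
         mean_absolute_error = sign(pred - target) / m)
}

optimizer_step <- function(state, grads, config, t) {
  lr <- config$learning_rate
  if (config$optimizer == "sgd") {
    state$delta <- lapply(grads, function(g) -lr * g)
  } else if (config$optimizer == "rmsprop") {
    rho <- 0.9; eps <- 1e-8
    for (i in seq_along(grads)) {
      state$v[[i]] <- rho * state$v[[i]] + (1 - rho) * grads[[i]]^2
      state$delta[[i]] <- -lr * grads[[i]] / (sqrt(state$v[[i]]) + eps)
    }
  } else {  # adam, conventional constants
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (i in seq_along(grads)) {
      state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * grads[[i]]
      state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * grads[[i]]^2
      mhat <- state$m[[i]] / (1 - b1^t)
      vhat <- state$v[[i]] / (1 - b2^t)
      state$delta[[i]] <- -lr * mhat / (sqrt(vhat) + eps)
    }
  }
  state
}

#' Train the network by minibatch gradient descent
#'
#' Runs the chosen optimizer for a fixed number of epochs with seeded
#' minibatch shuffling; there is no early stopping.  Rows labelled TE are
#' never used for weight updates; test metrics are computed once at the end.
#'
#' @param net a \code{\link{init_network}} network.
#' @param X feature matrix (all frames), rows in frame order.
#' @param targets scaled targets, one per frame.
#' @param labels per-frame labels from \code{\link{split_dataset}} ("TR"/"TE");
#'   \code{NULL} trains on every row.
#' @param config a \code{\link{training_config}}.
#' @return List with \code{net} (trained \code{network_spec}) and
#'   \code{history} (class \code{training_history}: per-epoch training loss,
#'   final test loss, Pearson r on TR and TE).
#' @export
train_network <- function(net, X, targets, labels = NULL,
                          config = training_config()) {
  X <- as.matrix(X)
  if (nrow(X) != length(targets)) stopf("X and targets disagree on row count")
  if (is.null(labels)) labels <- rep("TR", nrow(X))
  if (length(labels) != nrow(X)) stopf("labels and X disagree on row count")
  tr <- which(labels == "TR"); te <- which(labels == "TE")
  if (length(tr) < 1L) stopf("no training rows")
  Xtr <- X[tr, , drop = FALSE]; ttr <- targets[tr]
  ntr <- nrow(Xtr)
  params <- c(net$weights, net$biases)    # grads follow the same order
  zero_like <- lapply(params, function(p) p * 0)
  state <- list(m = zero_like, v = zero_like, delta = zero_like)
  nl <- length(net$weights)
  epoch_loss <- numeric(config$epochs)
  step <- 0L
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(ntr)
      starts <- seq.int(1L, ntr, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, ntr)]
        xb <- Xtr[idx, , drop = FALSE]; tb <- ttr[idx]
        fp <- forward_pass(net, xb)
        pred <- fp$a[[nl + 1L]][, 1L]
        if (!all(is.finite(pred))) {
          stopf("training diverged at epoch %d (non-finite prediction)", ep)
        }
        delta <- matrix(loss_grad(config$loss, pred, tb), ncol = 1L)
        gw <- vector("list", nl); gb <- vector("list", nl)
        for (l in nl:1) {
          dz <- delta * act_deriv(net$activations[l])(fp$z[[l]])
          gw[[l]] <- crossprod(fp$a[[l]], dz)
          gb[[l]] <- colSums(dz)
          if (l > 1L) delta <- dz %*% t(net$weights[[l]])
        }
        step <- step + 1L
        state <- optimizer_step(state, c(gw, gb), config, step)
        for (l in seq_len(nl)) {
          net$weights[[l]] <- net$weights[[l]] + state$delta[[l]]
          net$biases[[l]] <- net$biases[[l]] + drop(state$delta[[nl + l]])
        }
      }
      ep_loss <- loss_value(config$loss, forward(net, Xtr), ttr)
      if (!is.finite(ep_loss)) stopf("training diverged at epoch %d (non-finite loss)", ep)
      epoch_loss[ep] <- ep_loss
    }
  })
  pred_tr <- forward(net, Xtr)
  history <- structure(
    list(train_loss = epoch_loss,
         final_test_loss = if (length(te) > 0L)
           loss_value(config$loss, forward(net, X[te, , drop = FALSE]), targets[te])
         else NA_real_,
         pearson_tr = if (length(tr) >= 2L && stats::sd(pred_tr) > 0)
           stats::cor(pred_tr, ttr) else NA_real_,
         pearson_te = if (length(te) >= 2L) {
           pte <- forward(net, X[te, , drop = FALSE])
           if (stats::sd(pte) > 0) stats::cor(pte, targets[te]) else NA_real_
         } else NA_real_),
    class = "training_history")
  list(net = net, history = history)
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("<training_history> %d epochs; final TR loss %.3g; r(TR)=%.4f r(TE)=%.4f\n",
              length(x$train_loss),
              if (length(x$train_loss)) x$train_loss[length(x$train_loss)] else NA,
              x$pearson_tr, x$pearson_te))
  invisible(x)
}
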