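#' Multilayer-perceptron imputation
#'
#' A feed-forward network mapping a whole (possibly sparse) audiogram to all
#' of its thresholds at once. Observed inputs are scaled to \[0, 1\] (dB /
#' 120) and missing inputs encoded as -1; targets are the true values of the
#' sparse training rows, scaled likewise. Hidden layers use rectified-linear
#' activations and the output layer is linear; training minimizes mean
#' squared error over all outputs with minibatch Adam. With zero hidden
#' layers the network degenerates to a linear regression on the encoded
#' inputs. Missing query entries are filled from the network output,
#' rescaled and clipped to \[0, 120\] dB. Fully seeded: initialization and
#' minibatch order are reproducible.
#'
#' @param train Sparse training `audiogram_matrix` (the amputated inputs).
#' @param truth Dense `audiogram_matrix` with the true values of `train`.
#' @param query `audiogram_matrix` to complete.
#' @param hidden_layers Number of hidden layers (0 for the linear limit).
#' @param nodes_per_layer Width of each hidden layer.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer RNG seed.
#' @return Completed `audiogram_matrix`.
#' @export
impute_mlp <- function(train, truth, query, hidden_layers = 1L,
                       nodes_per_layer = 64L, learning_rate = 1e-3,
                       epochs = 200L, batch_size = 32L, seed = NULL) {
  fit <- fit_imputer(imputer_spec("NN", list(
    hidden_layers = as.integer(hidden_layers),
    nodes_per_layer = as.integer(nodes_per_layer),
    learning_rate = learning_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size))),
    train, truth = truth, seed = seed)
  impute(fit, query)
}

# encode thresholds for the network: observed -> dB/120, missing -> -1
mlp_encode <- function(values) {
  x <- values / 120
  x[is.na(x)] <- -1
  x
}

fit_mlp_state <- function(train, truth, hp, seed) {
  if (is.null(truth)) {
    stop("NN imputation is supervised: `truth` (the dense matrix whose ",
         "amputation produced `train`) is required", call. = FALSE)
  }
  X <- mlp_encode(unclass(train))
  Y <- unclass(truth) / 120
  stopifnot(all(dim(X) == dim(Y)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  net <- mlp_init(ncol(X), hp$hidden_layers, hp$nodes_per_layer, ncol(Y))
  net <- mlp_train(net, X, Y, lr = hp$learning_rate, epochs = hp$epochs,
                   batch_size = hp$batch_size)
  list(net = net)
}

#' @export
impute.fitted_NN <- function(object, query, ...) {
  X <- mlp_encode(unclass(query))
  filled <- mlp_forward(object$state$net, X)$a_out * 120
  finish_imputation(filled, query)
}

## ------------------------------------------------ tiny MLP internals ----

# He-initialized weights; layers: sizes[1] -> ... -> sizes[L]
mlp_init <- function(p_in, hidden_layers, width, p_out) {
  sizes <- c(p_in, rep(width, hidden_layers), p_out)
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b, L = L)
}

# forward pass; ReLU on hidden layers, identity on output
mlp_forward <- function(net, X) {
  a <- list(X)
  for (l in seq_len(net$L)) {
    z <- a[[l]] %*% net$W[[l]] + matrix(net$b[[l]], nrow(X),
                                        length(net$b[[l]]), byrow = TRUE)
    a[[l + 1]] <- if (l < net$L) pmax(z, 0) else z
  }
  list(a = a, a_out = a[[net$L + 1]])
}

mlp_train <- function(net, X, Y, lr, epochs, batch_size,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  n <- nrow(X)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  t <- 0
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      fw <- mlp_forward(net, X[idx, , drop = FALSE])
      # backprop of 0.5 * mean squared error over the batch
      delta <- (fw$a_out - Y[idx, , drop = FALSE]) / length(idx)
      t <- t + 1
      for (l in rev(seq_len(net$L))) {
        gW <- crossprod(fw$a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(net$W[[l]])) * (fw$a[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^t); vhW <- vW[[l]] / (1 - beta2^t)
        mhb <- mb[[l]] / (1 - beta1^t); vhb <- vb[[l]] / (1 - beta2^t)
        net$W[[l]] <- net$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        net$b[[l]] <- net$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  net
}
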