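# A compact multi-layer perceptron for binary classification.
#
# Architecture: fully connected hidden layers with rectified-linear
# activations and a sigmoid output unit, trained by mini-batch Adam on
# the binary cross-entropy. Written directly on R matrix operations:
# the problem sizes in this pipeline (hundreds to thousands of rows,
# tens to hundreds of features) fit comfortably in BLAS-backed matmuls.

mlp_init <- function(n_in, hidden, seed) {
  sizes <- c(n_in, hidden, 1L)
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1), function(i) {
      # He initialization for ReLU layers
      sd <- sqrt(2 / sizes[i])
      list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1], sd = sd),
                      sizes[i], sizes[i + 1]),
           b = rep(0, sizes[i + 1]))
    })
  })
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  n <- length(layers)
  for (i in seq_len(n)) {
    z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    acts[[i + 1]] <- if (i < n) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  acts
}

#' Fit a multi-layer perceptron classifier
#'
#' @param X numeric matrix (no missing values; scale features first).
#' @param y 0/1 vector.
#' @param hidden hidden layer widths (default two layers of 100 units).
#' @param epochs,batch_size,learning_rate Adam training parameters.
#' @param seed RNG seed for initialization and batch shuffling.
#' @return object of class `mlp_fit`.
#' @export
mlp_fit <- function(X, y, hidden = c(100, 100), epochs = 60, batch_size = 32,
                    learning_rate = 1e-3, seed = 1) {
  stopifnot(is.matrix(X), !anyNA(X), all(y %in% c(0, 1)))
  layers <- mlp_init(ncol(X), hidden, seed)
  nl <- length(layers)
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0
  n <- nrow(X)
  with_seed(seed + 1L, {
    for (epoch in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1, n)]
        Xb <- X[bi, , drop = FALSE]
        yb <- y[bi]
        acts <- mlp_forward(layers, Xb)
        nb <- length(bi)
        # dL/dz for sigmoid + cross-entropy
        delta <- (acts[[nl + 1]] - yb) / nb
        t <- t + 1
        for (i in rev(seq_len(nl))) {
          gW <- crossprod(acts[[i]], delta)
          gb <- colSums(delta)
          if (i > 1) {
            delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
          }
          m[[i]]$W <- beta1 * m[[i]]$W + (1 - beta1) * gW
          m[[i]]$b <- beta1 * m[[i]]$b + (1 - beta1) * gb
          v[[i]]$W <- beta2 * v[[i]]$W + (1 - beta2) * gW^2
          v[[i]]$b <- beta2 * v[[i]]$b + (1 - beta2) * gb^2
          mW <- m[[i]]$W / (1 - beta1^t); mb <- m[[i]]$b / (1 - beta1^t)
          vW <- v[[i]]$W / (1 - beta2^t); vb <- v[[i]]$b / (1 - beta2^t)
          layers[[i]]$W <- layers[[i]]$W - learning_rate * mW / (sqrt(vW) + eps)
          layers[[i]]$b <- layers[[i]]$b - learning_rate * mb / (sqrt(vb) + eps)
        }
      }
    }
  })
  structure(list(layers = layers, n_in = ncol(X)), class = "mlp_fit")
}

#' @rdname mlp_fit
#' @param object an `mlp_fit`.
#' @param newdata numeric matrix.
#' @param ... unused.
#' @return predicted probabilities of class 1.
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  stopifnot(ncol(newdata) == object$n_in)
  acts <- mlp_forward(object$layers, as.matrix(newdata))
  as.numeric(acts[[length(acts)]])
}
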