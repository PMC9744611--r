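# Minimal dense-network engine: Glorot-initialised fully connected layers,
# ReLU/linear activations, inverted dropout, mean-squared-error loss and the
# Adam optimiser.  All arithmetic is plain matrix algebra so a fit is
# bit-reproducible given the RNG seed; inference never uses dropout.
#
# Samples are rows throughout (n x p input).

nn_init <- function(layer_sizes) {
  n_map <- length(layer_sizes) - 1L
  layers <- vector("list", n_map)
  for (l in seq_len(n_map)) {
    fan_in <- layer_sizes[l]
    fan_out <- layer_sizes[l + 1L]
    limit <- sqrt(6 / (fan_in + fan_out))
    W <- matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
    layers[[l]] <- list(W = W, b = numeric(fan_out))
  }
  layers
}

nn_param_count <- function(layers) {
  sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

# activations: character vector, one per layer ("relu" or "linear").
# dropout: per-layer keep-rate handling — layers with dropout_after[l] TRUE
# get an inverted-dropout mask applied to their activation when training.
nn_forward <- function(layers, X, activations, dropout_after = NULL,
                       drop_rate = 0, training = FALSE) {
  n_map <- length(layers)
  A <- X
  As <- vector("list", n_map)   # post-activation (post-dropout) outputs
  Zs <- vector("list", n_map)
  Ms <- vector("list", n_map)   # dropout masks
  for (l in seq_len(n_map)) {
    Z <- sweep(A %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    A <- if (activations[l] == "relu") pmax(Z, 0) else Z
    if (training && drop_rate > 0 && isTRUE(dropout_after[l])) {
      M <- matrix(stats::rbinom(length(A), 1L, 1 - drop_rate) / (1 - drop_rate),
                  nrow(A), ncol(A))
      A <- A * M
      Ms[[l]] <- M
    }
    Zs[[l]] <- Z
    As[[l]] <- A
  }
  list(out = A, As = As, Zs = Zs, Ms = Ms)
}

# Gradient of mean((out - Y)^2) over all entries w.r.t. every W and b.
nn_backward <- function(layers, X, Y, fwd, activations) {
  n_map <- length(layers)
  n <- nrow(X)
  grads <- vector("list", n_map)
  delta <- 2 * (fwd$out - Y) / (n * ncol(Y))   # dL/dA_L
  for (l in rev(seq_len(n_map))) {
    if (!is.null(fwd$Ms[[l]])) delta <- delta * fwd$Ms[[l]]
    if (activations[l] == "relu") delta <- delta * (fwd$Zs[[l]] > 0)
    A_prev <- if (l == 1L) X else fwd$As[[l - 1L]]
    grads[[l]] <- list(W = crossprod(A_prev, delta), b = colSums(delta))
    if (l > 1L) delta <- delta %*% t(layers[[l]]$W)
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(layers, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[l]]$W <- layers[[l]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

nn_mse <- function(layers, X, activations) {
  out <- nn_forward(layers, X, activations, training = FALSE)$out
  mean((out - X)^2)
}
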