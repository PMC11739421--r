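# Internal multilayer perceptron with ReLU hidden layers, linear output,
# He initialization and Adam. Exposes forward/backward so deep kernel
# learning can backpropagate an arbitrary upstream gradient through the
# feature map; the DNN-ensemble members train on mean-squared error.

mlp_init <- function(dims, seed) {
  with_seed(seed, {
    layers <- vector("list", length(dims) - 1L)
    for (i in seq_along(layers)) {
      fan_in <- dims[i]
      layers[[i]] <- list(
        W = matrix(stats::rnorm(fan_in * dims[i + 1L], sd = sqrt(2 / fan_in)),
                   nrow = fan_in),
        b = numeric(dims[i + 1L]))
    }
    list(dims = dims, layers = layers)
  })
}

# returns list(out = n x d_out, cache = per-layer activations)
mlp_forward <- function(net, X) {
  L <- length(net$layers)
  cache <- vector("list", L)
  A <- X
  for (i in seq_len(L)) {
    Z <- A %*% net$layers[[i]]$W
    Z <- sweep(Z, 2, net$layers[[i]]$b, "+")
    cache[[i]] <- list(A_in = A, Z = Z)
    A <- if (i < L) pmax(Z, 0) else Z    # ReLU on hidden, linear output
  }
  list(out = A, cache = cache)
}

# dOut: gradient of the loss wrt the network output (n x d_out)
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- dOut
  for (i in rev(seq_len(L))) {
    if (i < L) delta <- delta * (cache[[i + 1L]]$A_in > 0)
    grads[[i]] <- list(W = crossprod(cache[[i]]$A_in, delta),
                       b = colSums(delta))
    if (i > 1L) delta <- delta %*% t(net$layers[[i]]$W)
  }
  grads
}

adam_state <- function(net) {
  lapply(net$layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    s <- state[[i]]
    g <- grads[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
    net$layers[[i]]$W <- net$layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# Full-batch MSE regression training with early stopping on the training
# loss plateau (patience in epochs).
mlp_train <- function(X, y, hidden = c(64, 32), epochs = 300, lr = 1e-2,
                      seed = 1, patience = 30, tol = 1e-7) {
  net <- mlp_init(c(ncol(X), hidden, 1L), seed = seed)
  state <- adam_state(net)
  n <- nrow(X)
  best <- Inf
  stall <- 0L
  for (t in seq_len(epochs)) {
    fw <- mlp_forward(net, X)
    resid <- drop(fw$out) - y
    loss <- mean(resid^2)
    if (!is.finite(loss)) {
      stop_alde("MLP training diverged (non-finite loss at epoch %d)", t,
                class = "alde_training_error")
    }
    grads <- mlp_backward(net, fw$cache, matrix(2 * resid / n, ncol = 1))
    upd <- adam_step(net, grads, state, lr, t)
    net <- upd$net
    state <- upd$state
    if (loss < best - tol) {
      best <- loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  net
}

mlp_predict <- function(net, X) drop(mlp_forward(net, X)$out)
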