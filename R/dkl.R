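#' Fit a deep-kernel-learning surrogate
#'
#' A Gaussian process whose covariance acts on a neural-network feature map:
#' `K(x, x') = k(phi_w(x), phi_w(x'))` with `k` a squared-exponential kernel
#' on the network outputs. The network weights are treated as kernel
#' hyperparameters and estimated jointly with the length scale, output scale
#' and noise variance by maximizing the log marginal likelihood (full-batch
#' Adam). This is the route for very high-dimensional encodings (e.g.
#' 1280-dim protein-language-model embeddings) where a plain GP fails.
#'
#' @param x numeric design matrix (any dimension; no cap applies).
#' @param y numeric fitness targets.
#' @param hidden hidden-layer widths of the feature network (ReLU), default
#'   `c(64, 32)`.
#' @param feature_dim output width of the feature map (default 8).
#' @param epochs full-batch Adam epochs (default 200).
#' @param lr learning rate (default 1e-2).
#' @param seed integer seed for weight initialization; fits are
#'   bit-reproducible given (data, spec, seed).
#' @param noise_floor lower bound on the noise variance.
#' @param identity_network if TRUE, freeze the feature map to the identity:
#'   the model reduces exactly to [fit_gp()] on the raw inputs (useful as a
#'   correctness check).
#' @param standardize z-standardize targets internally (default TRUE).
#' @return An `alde_posterior` with `model_kind = "dkl"`.
#' @export
fit_dkl <- function(x, y, hidden = c(64, 32), feature_dim = 8, epochs = 200,
                    lr = 1e-2, seed = 1, noise_floor = 1e-6,
                    identity_network = FALSE, standardize = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) < 2L || nrow(x) != length(y) || any(!is.finite(y))) {
    stop_alde("need >= 2 finite training rows with matching targets",
              class = "alde_contract_error")
  }
  if (identity_network) {
    p <- fit_gp(x, y, kernel = "rbf", noise_floor = noise_floor,
                standardize = standardize, max_dim = Inf)
    p$model_kind <- "dkl"
    p$input_dim <- ncol(x)
    return(p)
  }
  if (standardize) {
    ym <- mean(y); ys <- stats::sd(y)
    if (!is.finite(ys) || ys == 0) ys <- 1
  } else {
    ym <- 0; ys <- 1
  }
  z <- (y - ym) / ys
  n <- nrow(x)

  net <- mlp_init(c(ncol(x), hidden, feature_dim), seed = seed)
  state <- adam_state(net)
  # hyperparameters on log scale: lengthscale, outputscale, noise variance
  logpar <- log(c(1, 1, 1e-2))
  hm <- numeric(3); hv <- numeric(3)

  for (t in seq_len(epochs)) {
    fw <- mlp_forward(net, x)
    Z <- fw$out
    ls <- exp(logpar[1]); os <- exp(logpar[2])
    sn2 <- max(exp(logpar[3]), noise_floor)
    d2 <- outer(rowSums(Z^2), rowSums(Z^2), "+") - 2 * tcrossprod(Z)
    d2[d2 < 0] <- 0
    Kt <- os * exp(-0.5 * d2 / ls^2)
    K <- Kt + diag(sn2 + 1e-8, n)
    ch <- chol_jitter(K)
    alpha <- backsolve(ch$L, forwardsolve(t(ch$L), z))
    nll <- 0.5 * sum(z * alpha) + sum(log(diag(ch$L))) +
      0.5 * n * log(2 * pi)
    if (!is.finite(nll)) {
      stop_alde("deep-kernel training diverged (non-finite loss at epoch %d)",
                t, class = "alde_training_error")
    }
    Kinv <- chol2inv(ch$L)
    G <- 0.5 * (Kinv - tcrossprod(alpha))
    # gradient through the kernel into the feature space
    M <- G * Kt * (-0.5 / ls^2)
    dZ <- 4 * (rowSums(M) * Z - M %*% Z)
    grads <- mlp_backward(net, fw$cache, dZ)
    upd <- adam_step(net, grads, state, lr, t)
    net <- upd$net; state <- upd$state
    # hyperparameter gradients (wrt log parameters)
    hg <- c(sum(G * Kt * d2) / ls^2,
            sum(G * Kt),
            sn2 * sum(diag(G)))
    hm <- 0.9 * hm + 0.1 * hg
    hv <- 0.999 * hv + 0.001 * hg^2
    logpar <- logpar - lr * (hm / (1 - 0.9^t)) /
      (sqrt(hv / (1 - 0.999^t)) + 1e-8)
    logpar[3] <- max(logpar[3], log(noise_floor))
  }

  # final exact posterior on the learned feature space
  Z <- mlp_forward(net, x)$out
  ls <- exp(logpar[1]); os <- exp(logpar[2])
  sn2 <- max(exp(logpar[3]), noise_floor)
  K <- kernel_matrix(Z, Z, "rbf", ls, os) + diag(sn2, n)
  ch <- chol_jitter(K)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), z))
  net_local <- net
  structure(list(kind = "gp", model_kind = "dkl", X = Z, L = ch$L,
                 alpha = alpha, z_train = z, kernel = "rbf",
                 params = list(lengthscale = ls, outputscale = os,
                               noise = sn2, jitter = ch$jitter),
                 mu0 = 0, ym = ym, ys = ys, n_train = n,
                 input_dim = ncol(x),
                 transform = function(xnew) mlp_forward(net_local,
                                                        as.matrix(xnew))$out,
                 seed = seed),
            class = "alde_posterior")
}
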