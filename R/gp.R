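# Exact Gaussian-process regression with marginal-likelihood hyperparameter
# fitting, plus posterior function sampling via random Fourier features.
# This is the surrogate backbone; deep kernel learning reuses it on a
# network-transformed input space.

kernel_matrix <- function(X1, X2, kernel, lengthscale, outputscale) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  if (kernel == "rbf") {
    outputscale * exp(-0.5 * d2 / lengthscale^2)
  } else if (kernel == "matern52") {
    s <- sqrt(5) * sqrt(d2) / lengthscale
    outputscale * (1 + s + s^2 / 3) * exp(-s)
  } else {
    stop_alde("unknown kernel '%s'", kernel, class = "alde_unsupported_kernel_error")
  }
}

chol_jitter <- function(K) {
  for (j in c(0, 1e-8, 1e-6, 1e-4)) {
    R <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(R)) return(list(L = R, jitter = j))
  }
  stop_alde(paste0("kernel matrix is singular even after jitter escalation ",
                   "to 1e-4; increase the noise floor"),
            class = "alde_numerical_error")
}

gp_nll <- function(logpar, X, z, kernel, mu0) {
  ls <- exp(logpar[1]); os <- exp(logpar[2]); sn2 <- exp(logpar[3])
  K <- kernel_matrix(X, X, kernel, ls, os) + diag(sn2, nrow(X))
  ch <- tryCatch(chol_jitter(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  r <- z - mu0
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), r))
  val <- 0.5 * sum(r * alpha) + sum(log(diag(ch$L))) +
    0.5 * length(z) * log(2 * pi)
  if (!is.finite(val)) 1e10 else val
}

#' Fit an exact Gaussian-process surrogate
#'
#' Computes the standard GP regression posterior for targets observed under
#' i.i.d. additive Gaussian noise, `y_i = f(x_i) + eps_i`. Unless
#' hyperparameters are frozen, the length scale, output scale and noise
#' variance are estimated by maximizing the log marginal likelihood
#' (L-BFGS-B on log parameters). Targets are z-standardized internally and
#' predictions de-standardized on output.
#'
#' @param x numeric design matrix, one row per training variant (e.g. from
#'   [build_design_matrix()]).
#' @param y numeric fitness targets, one per row.
#' @param kernel `"matern52"` (default, shared length scale) or `"rbf"`.
#' @param lengthscale,outputscale,noise optional initial (or, with
#'   `fit_hyper = FALSE`, frozen) hyperparameters. `noise` is the noise
#'   variance.
#' @param fit_hyper maximize the marginal likelihood (default TRUE)?
#' @param prior_mean constant prior mean on the (standardized) target scale;
#'   default 0.
#' @param noise_floor lower bound on the noise variance (default 1e-6).
#' @param fit_budget optimizer iteration cap (default 100).
#' @param max_dim refuse feature dimensions above this (default 512):
#'   plain GPs degrade on very high-dimensional encodings such as
#'   protein-language-model embeddings; use [fit_dkl()] there.
#' @param standardize z-standardize targets internally (default TRUE).
#' @return An `alde_posterior` with `model_kind = "gp"`; see
#'   [posterior_stats()] and [sample_function()].
#' @export
fit_gp <- function(x, y, kernel = c("matern52", "rbf"), lengthscale = NULL,
                   outputscale = NULL, noise = NULL, fit_hyper = TRUE,
                   prior_mean = 0, noise_floor = 1e-6, fit_budget = 100,
                   max_dim = 512, standardize = TRUE) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) < 1L) {
    stop_alde("need at least one training row", class = "alde_contract_error")
  }
  if (nrow(x) != length(y) || any(!is.finite(y))) {
    stop_alde("inputs and targets disagree or targets are non-finite",
              class = "alde_contract_error")
  }
  if (ncol(x) > max_dim) {
    stop_alde(paste0("feature dimension %d exceeds the GP cap of %d ",
                     "(high-dimensional encodings need a deep kernel; ",
                     "see fit_dkl, or raise max_dim)"),
              ncol(x), max_dim, class = "alde_dimensionality_error")
  }
  if (standardize) {
    ym <- mean(y)
    ys <- stats::sd(y)
    if (!is.finite(ys) || ys == 0) ys <- 1
  } else {
    ym <- 0; ys <- 1
  }
  z <- (y - ym) / ys

  # initial hyperparameters: median heuristic for the length scale
  if (is.null(lengthscale)) {
    if (nrow(x) > 1L) {
      d <- stats::dist(x[seq_len(min(nrow(x), 200L)), , drop = FALSE])
      med <- stats::median(d[d > 0])
      lengthscale <- if (is.finite(med) && med > 0) med else 1
    } else {
      lengthscale <- 1
    }
  }
  outputscale <- outputscale %||% 1
  noise <- max(noise %||% 1e-2, noise_floor)

  logpar <- log(c(lengthscale, outputscale, noise))
  if (fit_hyper && nrow(x) >= 2L) {
    opt <- stats::optim(logpar, gp_nll, X = x, z = z, kernel = kernel,
                        mu0 = prior_mean, method = "L-BFGS-B",
                        lower = c(log(1e-3), log(1e-6), log(noise_floor)),
                        upper = c(log(1e3), log(1e3), log(10)),
                        control = list(maxit = fit_budget))
    logpar <- opt$par
  }
  ls <- exp(logpar[1]); os <- exp(logpar[2]); sn2 <- max(exp(logpar[3]), noise_floor)

  K <- kernel_matrix(x, x, kernel, ls, os) + diag(sn2, nrow(x))
  ch <- chol_jitter(K)
  r <- z - prior_mean
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), r))
  structure(list(kind = "gp", model_kind = "gp", X = x, L = ch$L,
                 alpha = alpha, z_train = z, kernel = kernel,
                 params = list(lengthscale = ls, outputscale = os,
                               noise = sn2, jitter = ch$jitter),
                 mu0 = prior_mean, ym = ym, ys = ys, n_train = nrow(x),
                 input_dim = ncol(x), transform = NULL),
            class = "alde_posterior")
}

#' @export
print.alde_posterior <- function(x, ...) {
  cat(sprintf("<alde_posterior> %s, %d training points\n",
              x$model_kind, x$n_train))
  invisible(x)
}

gp_stats <- function(p, x) {
  if (p$n_train == 0L) {
    return(list(mean = rep(p$ym + p$ys * p$mu0, nrow(x)),
                sd = rep(p$ys * sqrt(p$params$outputscale), nrow(x))))
  }
  ks <- kernel_matrix(x, p$X, p$kernel, p$params$lengthscale,
                      p$params$outputscale)
  mu <- p$mu0 + drop(ks %*% p$alpha)
  V <- forwardsolve(t(p$L), t(ks))
  var_f <- p$params$outputscale - colSums(V^2)
  var_f[var_f < 0] <- 0
  list(mean = p$ym + p$ys * mu, sd = p$ys * sqrt(var_f))
}

#' Gaussian-process prior (no data)
#'
#' A zero-observation posterior, mainly useful for checking the random
#' Fourier feature approximation against the analytic prior.
#'
#' @param d feature dimension.
#' @param kernel,lengthscale,outputscale,noise kernel family and
#'   hyperparameters as in [fit_gp()].
#' @return An `alde_posterior` with zero training points.
#' @export
gp_prior <- function(d, kernel = c("matern52", "rbf"), lengthscale = 1,
                     outputscale = 1, noise = 1e-6) {
  kernel <- match.arg(kernel)
  structure(list(kind = "gp", model_kind = "gp",
                 X = matrix(numeric(0), nrow = 0, ncol = d),
                 L = matrix(numeric(0), 0, 0), alpha = numeric(0),
                 z_train = numeric(0), kernel = kernel,
                 params = list(lengthscale = lengthscale,
                               outputscale = outputscale, noise = noise,
                               jitter = 0),
                 mu0 = 0, ym = 0, ys = 1, n_train = 0L, input_dim = d,
                 transform = NULL),
            class = "alde_posterior")
}

#' Posterior mean and standard deviation over candidates
#'
#' The single predictive contract shared by all surrogates: the Gaussian
#' process and deep-kernel models report the analytic posterior; ensembles
#' report the member mean and the sample (n-1) standard deviation.
#'
#' @param p an `alde_posterior` from [fit_gp()], [fit_dkl()] or
#'   [fit_ensemble()].
#' @param x candidate design matrix with the same encoding as training.
#' @return A list with numeric vectors `mean` and `sd` aligned with the
#'   candidate rows.
#' @export
posterior_stats <- function(p, x) {
  stopifnot(inherits(p, "alde_posterior"))
  x <- as.matrix(x)
  if (!is.null(p$input_dim) && ncol(x) != p$input_dim) {
    stop_alde("candidate dimension %d does not match training dimension %d",
              ncol(x), p$input_dim, class = "alde_contract_error")
  }
  if (!is.null(p$transform)) {
    out <- gp_stats_on(p, p$transform(x))
  } else if (p$kind == "gp") {
    if (ncol(x) != ncol(p$X)) {
      stop_alde("candidate dimension %d does not match training dimension %d",
                ncol(x), ncol(p$X), class = "alde_contract_error")
    }
    out <- gp_stats(p, x)
  } else if (p$kind == "ensemble") {
    preds <- ensemble_member_predictions(p, x)
    out <- list(mean = rowMeans(preds), sd = apply(preds, 1, stats::sd))
  } else {
    stop_alde("unknown posterior kind '%s'", p$kind,
              class = "alde_contract_error")
  }
  if (any(!is.finite(out$mean)) || any(!is.finite(out$sd))) {
    stop_alde("non-finite posterior statistics", class = "alde_numerical_error")
  }
  out
}

gp_stats_on <- function(p, z) {
  q <- p
  q$transform <- NULL
  if (ncol(z) != ncol(p$X)) {
    stop_alde("transformed candidate dimension %d does not match %d",
              ncol(z), ncol(p$X), class = "alde_contract_error")
  }
  gp_stats(q, z)
}

# Random Fourier feature map for a stationary kernel. Returns phi: n x D.
rff_features <- function(X, D, kernel, lengthscale, outputscale) {
  d <- ncol(X)
  if (kernel == "rbf") {
    W <- matrix(stats::rnorm(D * d), nrow = d) / lengthscale
  } else if (kernel == "matern52") {
    # Matern-5/2 spectral density: multivariate t with 5 degrees of freedom
    Z <- matrix(stats::rnorm(D * d), nrow = d)
    u <- stats::rchisq(D, df = 5)
    W <- sweep(Z, 2, sqrt(u / 5), "/") / lengthscale
  } else {
    stop_alde("random Fourier features need a stationary kernel, not '%s'",
              kernel, class = "alde_unsupported_kernel_error")
  }
  b <- stats::runif(D, 0, 2 * pi)
  sqrt(2 * outputscale / D) * cos(sweep(X %*% W, 2, b, "+"))
}

#' Draw one function realization from a posterior
#'
#' For GP and deep-kernel posteriors the sample is an approximate draw using
#' 1000 random Fourier features of the stationary kernel (weight-space
#' Bayesian linear regression on the features). For ensemble posteriors the
#' sample is the prediction vector of one uniformly drawn member. The same
#' seed always yields the same realization.
#'
#' @param p an `alde_posterior`.
#' @param x candidate design matrix.
#' @param seed integer seed for this draw.
#' @param n_features number of random Fourier features (GP/DKL; default
#'   1000).
#' @return Numeric vector: the sampled function evaluated at each candidate.
#' @export
sample_function <- function(p, x, seed, n_features = 1000) {
  stopifnot(inherits(p, "alde_posterior"))
  x <- as.matrix(x)
  if (p$kind == "ensemble") {
    return(with_seed(seed, {
      j <- sample.int(length(p$members), 1L)
      drop(ensemble_member_predictions(p, x, members = j))
    }))
  }
  z_cand <- if (!is.null(p$transform)) p$transform(x) else x
  with_seed(seed, {
    D <- n_features
    phi_all <- rff_features(rbind(p$X, z_cand), D, p$kernel,
                            p$params$lengthscale, p$params$outputscale)
    n <- nrow(p$X)
    phi_tr <- phi_all[seq_len(n), , drop = FALSE]
    phi_cd <- phi_all[n + seq_len(nrow(z_cand)), , drop = FALSE]
    if (n == 0L) {
      theta <- stats::rnorm(D)
    } else {
      sn2 <- p$params$noise
      A <- crossprod(phi_tr) + diag(sn2, D)
      cA <- chol(A)
      m <- backsolve(cA, forwardsolve(t(cA),
                                      crossprod(phi_tr, p$z_train - p$mu0)))
      # theta ~ N(m, sn2 * A^-1): draw via A = R'R, cov = sn2 R^-1 R^-T
      eta <- stats::rnorm(D)
      theta <- drop(m) + sqrt(sn2) * drop(backsolve(cA, eta))
    }
    p$ym + p$ys * (p$mu0 + drop(phi_cd %*% theta))
  })
}
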