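# Independent textbook GP-regression oracle: direct evaluation of the
# closed-form posterior mean/variance with solve(), no Cholesky, no
# standardization, written only from the standard identities.
gp_oracle <- function(Xtr, y, Xte, lengthscale, outputscale, noise) {
  matern52 <- function(a, b) {
    r <- sqrt(sum((a - b)^2))
    s <- sqrt(5) * r / lengthscale
    outputscale * (1 + s + s^2 / 3) * exp(-s)
  }
  n <- nrow(Xtr)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) matern52(Xtr[i, ], Xtr[j, ])))
  Kinv <- solve(K + noise * diag(n))
  mu <- numeric(nrow(Xte))
  sd <- numeric(nrow(Xte))
  for (t in seq_len(nrow(Xte))) {
    ks <- vapply(seq_len(n), function(i) matern52(Xte[t, ], Xtr[i, ]),
                 numeric(1))
    mu[t] <- sum(ks * (Kinv %*% y))
    v <- outputscale - drop(t(ks) %*% Kinv %*% ks)
    sd[t] <- sqrt(max(v, 0))
  }
  list(mean = mu, sd = sd)
}

gp_fixture <- function() {
  with_seed(42, list(Xtr = matrix(rnorm(3 * 2), nrow = 3),
                     y = c(0.2, 0.9, 0.4),
                     Xte = matrix(rnorm(5 * 2), nrow = 5)))
}

test_that("frozen-hyperparameter GP matches the textbook oracle to 1e-8", {
  fx <- gp_fixture()
  hp <- list(lengthscale = 0.8, outputscale = 1.3, noise = 1e-4)
  p <- fit_gp(fx$Xtr, fx$y, kernel = "matern52",
              lengthscale = hp$lengthscale, outputscale = hp$outputscale,
              noise = hp$noise, fit_hyper = FALSE, standardize = FALSE)
  st <- posterior_stats(p, fx$Xte)
  or <- gp_oracle(fx$Xtr, fx$y, fx$Xte, hp$lengthscale, hp$outputscale,
                  hp$noise)
  expect_lt(max(abs(st$mean - or$mean)), 1e-8)
  expect_lt(max(abs(st$sd - or$sd)), 1e-8)
})

test_that("GP interpolates a single training point at the noise floor", {
  p <- fit_gp(matrix(c(0.3, 0.7), nrow = 1), 2.5, noise = 1e-6,
              fit_hyper = FALSE, standardize = FALSE, prior_mean = 0)
  st <- posterior_stats(p, matrix(c(0.3, 0.7), nrow = 1))
  expect_lt(abs(st$mean - 2.5), 1e-5)
  expect_error(fit_gp(matrix(numeric(0), nrow = 0, ncol = 2), numeric(0)),
               class = "alde_contract_error")
})

test_that("GP uncertainty grows away from the training data", {
  fx <- gp_fixture()
  p <- fit_gp(fx$Xtr, fx$y, lengthscale = 1, outputscale = 1, noise = 1e-6,
              fit_hyper = FALSE, standardize = FALSE)
  near <- posterior_stats(p, fx$Xtr)
  far <- posterior_stats(p, fx$Xtr + 50)
  expect_true(all(near$sd < far$sd))
  expect_true(all(near$sd < 1e-2))
})

test_that("GP refuses very high-dimensional inputs; DKL handles them", {
  X <- with_seed(3, matrix(rnorm(50 * 1280), nrow = 50))
  y <- with_seed(4, rnorm(50))
  expect_error(fit_gp(X, y), class = "alde_dimensionality_error")
  p <- fit_dkl(X, y, epochs = 30, seed = 1)
  cand <- with_seed(5, matrix(rnorm(1000 * 1280), nrow = 1000))
  st <- posterior_stats(p, cand)
  expect_true(all(is.finite(st$mean)) && all(is.finite(st$sd)))
  expect_length(st$mean, 1000)
})

test_that("identity-network DKL reduces to the GP and fits are seeded", {
  fx <- gp_fixture()
  X <- with_seed(6, matrix(rnorm(20 * 4), nrow = 20))
  y <- with_seed(7, rnorm(20))
  pid <- fit_dkl(X, y, identity_network = TRUE)
  pgp <- fit_gp(X, y, kernel = "rbf", max_dim = Inf)
  sid <- posterior_stats(pid, X)
  sgp <- posterior_stats(pgp, X)
  expect_equal(sid$mean, sgp$mean, tolerance = 1e-6)
  expect_equal(sid$sd, sgp$sd, tolerance = 1e-6)

  p1 <- fit_dkl(X, y, epochs = 50, seed = 11)
  p2 <- fit_dkl(X, y, epochs = 50, seed = 11)
  expect_identical(posterior_stats(p1, X), posterior_stats(p2, X))
})

test_that("ensemble members train on exactly the bootstrap fraction", {
  X <- with_seed(8, matrix(rnorm(100 * 5), nrow = 100))
  y <- with_seed(9, rnorm(100))
  p <- fit_ensemble(X, y, base_learner = "boosting", seed = 1)
  expect_length(p$members, 5)
  expect_true(all(lengths(p$member_rows) == 90))
  # without replacement: no duplicated rows within a member
  expect_true(all(vapply(p$member_rows,
                         function(r) !anyDuplicated(r), logical(1))))
})

test_that("ensemble mean/sd follow the member-spread contract", {
  x <- matrix(0, nrow = 1, ncol = 2)
  p <- constant_member_posterior(c(1, 2, 3))
  st <- posterior_stats(p, x)
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)  # sample (n-1) standard deviation
  p5 <- constant_member_posterior(c(1, 2, 3, 4, 5))
  expect_equal(posterior_stats(p5, x)$mean, 3)
  # member order does not matter
  pshuf <- constant_member_posterior(c(3, 1, 2))
  expect_equal(posterior_stats(pshuf, x), st)
})

test_that("disabling the bootstrap with a deterministic learner collapses sigma", {
  X <- with_seed(10, matrix(rnorm(30 * 4), nrow = 30))
  y <- with_seed(11, rnorm(30))
  p <- fit_ensemble(X, y, base_learner = "boosting", bootstrap_fraction = 1,
                    seed = 1)
  st <- posterior_stats(p, X)
  expect_true(all(st$sd < 1e-10))
  # Thompson sampling degenerates to the mean
  s <- sample_function(p, X, seed = 1)
  expect_equal(s, st$mean, tolerance = 1e-10)
})

test_that("ensembles track a constant target", {
  X <- with_seed(12, matrix(rnorm(40 * 4), nrow = 40))
  y <- rep(0.7, 40)
  # tolerance is learner-dependent: boosted trees fit a constant exactly,
  # the MLP approaches it by gradient descent
  tol <- c(boosting = 1e-6, dnn = 0.1)
  for (bl in c("dnn", "boosting")) {
    p <- fit_ensemble(X, y, base_learner = bl, seed = 2)
    st <- posterior_stats(p, X)
    expect_lt(max(abs(st$mean - 0.7)), tol[[bl]])
  }
})

test_that("an ensemble function sample is exactly one member's prediction", {
  preds <- list(c(1, 5, 2), c(4, 0, 3), c(2, 2, 2), c(0, 1, 9), c(7, 1, 1))
  p <- vector_member_posterior(preds)
  x <- matrix(0, nrow = 3, ncol = 2)
  for (seed in 1:20) {
    s <- sample_function(p, x, seed = seed)
    expect_true(any(vapply(preds, function(v) identical(s, v), logical(1))))
  }
  # seeded determinism
  expect_identical(sample_function(p, x, seed = 3),
                   sample_function(p, x, seed = 3))
})

test_that("random Fourier prior samples match the analytic prior variance", {
  cand <- with_seed(13, matrix(rnorm(5 * 2), nrow = 5))
  p <- gp_prior(2, kernel = "rbf", lengthscale = 1, outputscale = 1.5)
  draws <- vapply(seq_len(2000),
                  function(s) sample_function(p, cand, seed = s),
                  numeric(5))
  v <- apply(draws, 1, var)
  expect_true(all(abs(v - 1.5) / 1.5 < 0.10))
  expect_lt(max(abs(rowMeans(draws))), 0.15)
})

test_that("more training data does not hurt ensemble accuracy on average", {
  l <- additive_landscape()
  enc <- onehot_encoder(l$alphabet)
  combos <- names(l$fitness)
  Xall <- build_design_matrix(combos, enc)
  mae_at <- function(n, seed) {
    idx <- with_seed(seed, sample(length(combos), n))
    p <- fit_ensemble(Xall[idx, ], l$fitness[idx], base_learner = "boosting",
                      seed = seed)
    mean(abs(posterior_stats(p, Xall)$mean - l$fitness))
  }
  m_small <- mean(vapply(1:10, function(s) mae_at(16, s), numeric(1)))
  m_large <- mean(vapply(1:10, function(s) mae_at(48, s), numeric(1)))
  expect_lte(m_large, m_small)
})
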