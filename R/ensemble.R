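#' Fit a bootstrapped ensemble surrogate
#'
#' Trains an ensemble of independent regressors and treats their spread as
#' predictive uncertainty: the posterior mean is the arithmetic member mean
#' and the standard deviation is the sample (n-1) standard deviation across
#' members. Each member sees its own uniform subsample without replacement
#' of `floor(bootstrap_fraction * n)` training rows (default 90%), and
#' members additionally differ by seeded weight initialization.
#'
#' Two base learners are available:
#' * `"dnn"` — multilayer perceptrons (ReLU, hidden widths `c(64, 32)`,
#'   full-batch Adam on mean-squared error, 300 epochs, early-stop patience
#'   30), trained by the package's own implementation.
#' * `"boosting"` — gradient-boosted trees via \pkg{xgboost} (100 rounds,
#'   depth 3, learning rate 0.1, single-threaded for reproducibility).
#'
#' @param x numeric design matrix.
#' @param y numeric fitness targets.
#' @param base_learner `"dnn"` or `"boosting"`.
#' @param n_members ensemble size (default 5).
#' @param bootstrap_fraction fraction of training rows each member sees
#'   (default 0.9; 1 disables subsampling).
#' @param seed integer seed; member subsamples and initializations derive
#'   sub-seeds from it.
#' @param member_config named list of base-learner overrides (`hidden`,
#'   `epochs`, `lr`, `patience` for dnn; `nrounds`, `max_depth`, `eta` for
#'   boosting).
#' @param standardize z-standardize targets internally (default TRUE).
#' @return An `alde_posterior` with `model_kind` `"dnn_ensemble"` or
#'   `"boosting_ensemble"`; `member_rows` records each member's training
#'   rows.
#' @export
fit_ensemble <- function(x, y, base_learner = c("dnn", "boosting"),
                         n_members = 5, bootstrap_fraction = 0.9, seed = 1,
                         member_config = list(), standardize = TRUE) {
  base_learner <- match.arg(base_learner)
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(n_members >= 2, bootstrap_fraction > 0, bootstrap_fraction <= 1)
  if (n != length(y) || any(!is.finite(y))) {
    stop_alde("inputs and targets disagree or targets are non-finite",
              class = "alde_contract_error")
  }
  m_rows <- floor(bootstrap_fraction * n)
  if (m_rows < 1L) {
    stop_alde("bootstrap_fraction %.3g leaves no training rows at n=%d",
              bootstrap_fraction, n, class = "alde_contract_error")
  }
  if (standardize) {
    ym <- mean(y); ys <- stats::sd(y)
    if (!is.finite(ys) || ys == 0) ys <- 1
  } else {
    ym <- 0; ys <- 1
  }
  z <- (y - ym) / ys

  members <- vector("list", n_members)
  member_rows <- vector("list", n_members)
  failures <- character(0)
  for (j in seq_len(n_members)) {
    rows <- if (m_rows == n) seq_len(n) else {
      with_seed(derive_seed(seed, 101L, j), sort(sample.int(n, m_rows)))
    }
    member_rows[[j]] <- rows
    fit <- tryCatch({
      if (base_learner == "dnn") {
        net <- mlp_train(x[rows, , drop = FALSE], z[rows],
                         hidden = member_config$hidden %||% c(64, 32),
                         epochs = member_config$epochs %||% 300,
                         lr = member_config$lr %||% 1e-2,
                         patience = member_config$patience %||% 30,
                         seed = derive_seed(seed, 202L, j))
        list(kind = "dnn", net = net)
      } else {
        bst <- xgboost::xgboost(
          x[rows, , drop = FALSE], z[rows],
          nrounds = member_config$nrounds %||% 100,
          max_depth = member_config$max_depth %||% 3,
          learning_rate = member_config$eta %||% 0.1,
          objective = "reg:squarederror", nthreads = 1,
          verbosity = 0, seed = derive_seed(seed, 202L, j))
        list(kind = "boosting", model = bst)
      }
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("member %d: %s", j, conditionMessage(fit)))
    } else {
      members[[j]] <- fit
    }
  }
  if (length(failures) > 0L) {
    stop_alde("ensemble training failed in %d member(s): %s",
              length(failures), paste(failures, collapse = "; "),
              class = "alde_training_error")
  }
  structure(list(kind = "ensemble",
                 model_kind = paste0(base_learner, "_ensemble"),
                 members = members, member_rows = member_rows,
                 bootstrap_fraction = bootstrap_fraction,
                 ym = ym, ys = ys, n_train = n, input_dim = ncol(x),
                 seed = seed),
            class = "alde_posterior")
}

# n_cand x n_members matrix of de-standardized member predictions
ensemble_member_predictions <- function(p, x, members = seq_along(p$members)) {
  x <- as.matrix(x)
  preds <- vapply(members, function(j) {
    m <- p$members[[j]]
    zhat <- if (m$kind == "dnn") {
      mlp_predict(m$net, x)
    } else if (m$kind == "boosting") {
      stats::predict(m$model, x)
    } else if (m$kind == "fixed") {
      # stub member holding a fixed prediction function (used in tests)
      m$predict(x)
    } else {
      stop_alde("unknown member kind '%s'", m$kind,
                class = "alde_contract_error")
    }
    as.numeric(zhat)
  }, numeric(nrow(x)))
  p$ym + p$ys * matrix(preds, nrow = nrow(x))
}
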