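#' Calibration curve of a Gaussian predictive distribution
#'
#' For each nominal coverage level p, computes the fraction of true values
#' falling inside the central-p Gaussian interval
#' `mean +/- z((1+p)/2) * std`. A calibrated model's curve tracks the
#' diagonal: an n% confidence interval should contain n% of true labels.
#'
#' @param mean,std,truth aligned finite numeric vectors (`std >= 0`).
#' @param levels nominal coverage grid in \[0, 1\], strictly increasing.
#'   Default: 101 evenly spaced levels from 0 to 1.
#' @return A list with `levels` and `observed` coverage fractions.
#' @export
calibration_curve <- function(mean, std, truth,
                              levels = seq(0, 1, length.out = 101)) {
  n <- length(truth)
  if (n == 0L || length(mean) != n || length(std) != n) {
    stop_alde("mean, std and truth must be nonempty and aligned",
              class = "alde_contract_error")
  }
  if (any(std < 0)) {
    stop_alde("negative standard deviations", class = "alde_contract_error")
  }
  absdev <- abs(truth - mean)
  observed <- vapply(levels, function(p) {
    if (p >= 1) return(1)
    z <- stats::qnorm((1 + p) / 2)
    mean(absdev <= z * std)
  }, numeric(1))
  list(levels = levels, observed = observed)
}

#' Miscalibration area
#'
#' The area between a calibration curve and perfect calibration (the
#' diagonal), computed as the trapezoidal integral of
#' `|observed(p) - p|` over p in \[0, 1\] with the endpoints (0,0) and
#' (1,1) appended. 0 means perfect calibration; a totally overconfident
#' predictor (zero-width intervals) approaches 0.5.
#'
#' @param levels,observed a calibration curve (see [calibration_curve()]).
#' @return Nonnegative scalar.
#' @export
miscalibration_area <- function(levels, observed) {
  stopifnot(length(levels) == length(observed))
  p <- c(0, levels, 1)
  o <- c(0, observed, 1)
  keep <- !duplicated(p)
  p <- p[keep]; o <- o[keep]
  ord <- order(p)
  p <- p[ord]; o <- o[ord]
  d <- abs(o - p)
  sum(diff(p) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
}

#' Spearman correlation between uncertainty and error
#'
#' Rank correlation between the model's predictive standard deviations and
#' its per-point absolute errors; high values mean the model knows where it
#' is wrong. Ties are handled by average ranks. If either vector is
#' constant, the correlation is reported as 0 with attribute
#' `degenerate = TRUE` rather than an error.
#'
#' @param std predictive standard deviations.
#' @param abs_error per-point absolute errors.
#' @return Scalar in \[-1, 1\].
#' @export
uncertainty_error_spearman <- function(std, abs_error) {
  n <- length(std)
  if (n != length(abs_error) || n < 3L) {
    stop_alde("need >= 3 aligned points", class = "alde_contract_error")
  }
  if (stats::sd(std) == 0 || stats::sd(abs_error) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  unname(stats::cor(std, abs_error, method = "spearman"))
}

#' Evaluate a surrogate's uncertainty quality against a landscape
#'
#' Predicts every measured variant of the landscape (training points
#' included, matching the protocol of scoring a campaign's final-round
#' model on all measured points of the design space) and reports the mean
#' absolute error, the calibration curve and its miscalibration area under
#' a Gaussian interval assumption, and the Spearman correlation between
#' predictive standard deviation and absolute error.
#'
#' @param p an `alde_posterior`.
#' @param l an [landscape()] object (the measured set is the evaluation
#'   set).
#' @param encoder the `alde_encoder` the surrogate was trained with.
#' @param levels coverage grid (see [calibration_curve()]).
#' @return An `alde_calibration_report`: list with `mae`,
#'   `miscalibration_area`, `spearman_sigma_error`, `levels`, `observed`,
#'   and `n_points`.
#' @export
evaluate_model_calibration <- function(p, l, encoder,
                                       levels = seq(0, 1, length.out = 101)) {
  combos <- names(l$fitness)
  x <- build_design_matrix(combos, encoder)
  st <- posterior_stats(p, x)
  truth <- unname(l$fitness)
  err <- abs(st$mean - truth)
  curve <- calibration_curve(st$mean, st$sd, truth, levels = levels)
  structure(list(mae = mean(err),
                 miscalibration_area = miscalibration_area(curve$levels,
                                                           curve$observed),
                 spearman_sigma_error = uncertainty_error_spearman(st$sd, err),
                 levels = curve$levels, observed = curve$observed,
                 n_points = length(truth)),
            class = "alde_calibration_report")
}

#' @export
print.alde_calibration_report <- function(x, ...) {
  cat(sprintf(paste0("<alde_calibration_report> n=%d points\n",
                     "  MAE %.4f | miscalibration area %.4f | ",
                     "Spearman(sigma, |error|) %.3f\n"),
              x$n_points, x$mae, x$miscalibration_area,
              as.numeric(x$spearman_sigma_error)))
  invisible(x)
}
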