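# Ensemble aggregation and error metrics: the per-point ensemble mean, the
# reported MAE/RMSE of the ensemble prediction, the unbiased per-point
# spread of the submodel predictions, and Student-t confidence intervals.

#' Ensemble prediction block
#'
#' Container for the predictions of `N_ens` submodels on `N_test` records,
#' together with the targets. Submodels share the data split and differ only
#' in initialization, so the block has a single split index.
#'
#' @param predictions numeric matrix, rows = submodels, columns = records.
#' @param targets numeric vector of length `ncol(predictions)`.
#' @return an object of class `ensemble_block`.
#' @export
ensemble_block <- function(predictions, targets) {
  predictions <- as.matrix(predictions)
  stopifnot(is.numeric(predictions), is.numeric(targets),
            ncol(predictions) == length(targets),
            nrow(predictions) >= 1L)
  if (anyNA(predictions) || anyNA(targets))
    stop("ensemble block must not contain missing values")
  structure(list(predictions = predictions, targets = as.numeric(targets),
                 n_ens = nrow(predictions), n_test = ncol(predictions)),
            class = "ensemble_block")
}

#' @export
print.ensemble_block <- function(x, ...) {
  cat(sprintf("<ensemble_block: %d submodels x %d records>\n",
              x$n_ens, x$n_test))
  invisible(x)
}

#' Per-point ensemble mean
#'
#' Arithmetic mean of the submodel predictions for each test record.
#'
#' @param b an [ensemble_block()].
#' @return numeric vector of length `N_test`.
#' @export
ensemble_mean <- function(b) {
  stopifnot(inherits(b, "ensemble_block"))
  colMeans(b$predictions)
}

#' Reported ensemble errors
#'
#' MAE and RMSE of the ensemble-mean prediction against the targets,
#' averaged over the test records.
#'
#' @param b an [ensemble_block()].
#' @return list with `mae` and `rmse`.
#' @export
ensemble_errors <- function(b) {
  r <- ensemble_mean(b) - b$targets
  list(mae = mean(abs(r)), rmse = sqrt(mean(r^2)))
}

#' Per-point unbiased ensemble spread
#'
#' Sample standard deviation (divisor `N_ens - 1`) of the submodel
#' predictions for each record.
#'
#' @param b an [ensemble_block()].
#' @return numeric vector of length `N_test`.
#' @export
ensemble_std <- function(b) {
  stopifnot(inherits(b, "ensemble_block"))
  if (b$n_ens < 2L)
    stop("ensemble spread is undefined for fewer than 2 submodels")
  apply(b$predictions, 2L, stats::sd)
}

#' Student-t confidence interval around the ensemble mean
#'
#' Interval `mean +/- t * s`, where `t` is the two-sided Student-t factor at
#' confidence `p` with `N_ens - 1` degrees of freedom. By default the spread
#' `s` is used directly (the interval for a single model-family draw, the
#' convention used for coverage-based calibration); `scale = "sem"` divides
#' by `sqrt(N_ens)` instead.
#'
#' @param mean,s numeric vectors: per-point ensemble mean and spread.
#' @param n_ens ensemble size (`>= 2`).
#' @param p confidence level in (0,1).
#' @param scale `"s"` (default) or `"sem"`.
#' @return list with vectors `lower` and `upper`.
#' @export
confidence_interval <- function(mean, s, n_ens, p, scale = c("s", "sem")) {
  scale <- match.arg(scale)
  if (n_ens < 2L) stop("confidence interval needs at least 2 submodels")
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1))
    stop("confidence p must lie strictly inside (0, 1)")
  tfac <- stats::qt((1 + p) / 2, df = n_ens - 1L)
  half <- tfac * s / if (scale == "sem") sqrt(n_ens) else 1
  list(lower = mean - half, upper = mean + half)
}
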