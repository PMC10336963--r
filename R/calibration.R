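# Confidence-based calibration: coverage curves over nominal confidence
# levels, the area under the calibration error curve (AUCE), single-scalar
# uncertainty rescaling, and sharpness / dispersion diagnostics.

#' Confidence-based calibration curve
#'
#' For each nominal confidence `p`, the empirical coverage is the fraction
#' of records whose target lies inside the `p` confidence interval around
#' the predicted value. Ensemble inputs use Student-t intervals with
#' `N_ens - 1` degrees of freedom (see [confidence_interval()]); for
#' mean-variance estimation inputs (`quantile = "normal"`), the normal
#' quantile replaces the t factor and `stds` are the predicted sigmas.
#'
#' @param means,stds,targets numeric vectors: per-record predicted mean,
#'   uncertainty, and true target.
#' @param n_ens ensemble size, required for `quantile = "t"`.
#' @param p_grid strictly increasing confidence grid inside (0,1).
#' @param quantile `"t"` or `"normal"`.
#' @param scale interval scaling convention, see [confidence_interval()].
#' @return an object of class `calibration_curve`: data frame `p`,
#'   `coverage` plus convention metadata.
#' @export
calibration_curve <- function(means, stds, targets, n_ens = NULL,
                              p_grid = seq(0.01, 0.99, by = 0.01),
                              quantile = c("t", "normal"),
                              scale = c("s", "sem")) {
  quantile <- match.arg(quantile)
  scale <- match.arg(scale)
  n <- length(targets)
  if (n == 0L) stop("calibration needs at least one record")
  stopifnot(length(means) == n, length(stds) == n, all(stds >= 0),
            all(diff(p_grid) > 0), all(p_grid > 0), all(p_grid < 1))
  if (quantile == "t" && (is.null(n_ens) || n_ens < 2L))
    stop("t-quantile calibration needs n_ens >= 2")
  fac <- if (quantile == "t") stats::qt((1 + p_grid) / 2, df = n_ens - 1L)
  else stats::qnorm((1 + p_grid) / 2)
  if (scale == "sem") fac <- fac / sqrt(n_ens)
  z <- abs(targets - means)
  coverage <- vapply(fac, function(f) mean(z <= f * stds), numeric(1))
  structure(list(curve = data.frame(p = p_grid, coverage = coverage),
                 n_test = n,
                 convention = paste0(quantile, "/", scale)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve: %d levels, %d records, %s, AUCE %.4f>\n",
              nrow(x$curve), x$n_test, x$convention, auce(x)))
  invisible(x)
}

#' Area under the calibration error curve
#'
#' Trapezoidal integral of `|coverage(p) - p|` over `p` in `[0, 1]`, with the
#' observed curve extended to the endpoints by constant continuation. 0 is
#' perfect calibration; the closed-form extremes `coverage == 0` and
#' `coverage == 1` both give 0.5.
#'
#' @param c a [calibration_curve()].
#' @return scalar `>= 0`.
#' @export
auce <- function(c) {
  stopifnot(inherits(c, "calibration_curve"))
  p <- c(0, c$curve$p, 1)
  cov <- c(c$curve$coverage[1L], c$curve$coverage,
           c$curve$coverage[nrow(c$curve)])
  e <- abs(cov - p)
  sum((e[-1L] + e[-length(e)]) / 2 * diff(p))
}

#' Rescale uncertainties to a reference average
#'
#' Multiplies all uncertainties by one scalar so that their mean equals
#' `reference_mean`. Used to put ensemble spreads on the same average scale
#' as a competing uncertainty method before comparing regime means.
#'
#' @param unc numeric vector with positive mean.
#' @param reference_mean target average.
#' @return rescaled vector, `mean(out) == reference_mean`.
#' @export
scale_uncertainty <- function(unc, reference_mean) {
  m <- mean(unc)
  if (!is.finite(m) || m <= 0)
    stop("cannot rescale uncertainties with non-positive mean")
  unc * (reference_mean / m)
}

#' Sharpness and dispersion of an uncertainty estimate
#'
#' Sharpness is the average predicted uncertainty (lower is sharper at equal
#' calibration); dispersion is its coefficient of variation (the ability to
#' separate high- from low-uncertainty records).
#'
#' @param unc nonnegative numeric vector of predicted uncertainties.
#' @return list with `sharpness` and `dispersion`.
#' @export
sharpness_dispersion <- function(unc) {
  if (!length(unc)) stop("empty uncertainty vector")
  stopifnot(all(unc >= 0))
  m <- mean(unc)
  if (m == 0) stop("dispersion is undefined for all-zero uncertainties")
  list(sharpness = m, dispersion = stats::sd(unc) / m)
}
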