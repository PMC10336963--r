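# Empirical-Bayes decomposition of the ensemble error into variance and
# nonvariance (bias) contributions. Submodel predictions for a record are
# modeled as normal draws around an unknown mean mu_n; the nonvariance error
# is E|mu_n - y_n| (the absolute error a very large ensemble would still
# make) and the variance error is |ybar_n - y_n| minus that. The per-point
# posterior over b_n = mu_n - y_n is computed on a shared grid with a
# dataset-level prior that is refined iteratively (prior <- mean posterior).

#' Infer the variance / nonvariance error decomposition
#'
#' For each record the observed ensemble residual `d_n = ybar_n - y_n` and
#' spread `s_n` define a likelihood for the latent bias `b_n = mu_n - y_n`:
#' by default the Student-t form with `N_ens - 1` degrees of freedom and
#' scale `s_n / sqrt(N_ens)` (the unknown within-ensemble spread is
#' marginalized; a plug-in normal variant is available). The prior over `b`
#' is initialized from the empirical distribution of the residuals and
#' refined by empirical-Bayes iteration until its L1 change falls below
#' `tol` or `max_iter` is reached.
#'
#' @param b an [ensemble_block()] with `N_ens >= 2`.
#' @param grid_points number of grid points for the posterior.
#' @param grid_mult half-width of the grid in units of the robust residual
#'   standard deviation (widened if residuals exceed it).
#' @param max_iter,tol stopping rule for the prior refinement.
#' @param likelihood `"t"` (default) or `"normal"` (plug-in spread).
#' @return an object of class `decomposition_result`: per-point data frame
#'   (`residual`, `nonvariance`, `variance`), dataset means
#'   `mean_nonvariance` and `mean_variance`, the ensemble `mae`, iteration
#'   diagnostics and the final prior.
#' @export
infer_decomposition <- function(b, grid_points = 801L, grid_mult = 8,
                                max_iter = 20L, tol = 1e-4,
                                likelihood = c("t", "normal")) {
  stopifnot(inherits(b, "ensemble_block"))
  likelihood <- match.arg(likelihood)
  if (b$n_ens < 2L) stop("decomposition needs at least 2 submodels")
  d <- ensemble_mean(b) - b$targets
  s <- ensemble_std(b)
  n <- length(d)
  scale <- s / sqrt(b$n_ens)
  degenerate <- scale < 1e-12
  if (all(degenerate)) {
    warning("all ensemble spreads are zero; returning the point-mass limit")
    per <- data.frame(residual = d, nonvariance = abs(d), variance = 0)
    return(new_decomposition(per, iterations = 0L, prior = NULL,
                             grid = NULL, l1_trace = numeric(0)))
  }
  rsd <- stats::mad(d)
  if (!is.finite(rsd) || rsd == 0) rsd <- stats::sd(d)
  if (!is.finite(rsd) || rsd == 0) rsd <- max(abs(d), 1e-6)
  span <- max(grid_mult * rsd, 1.05 * max(abs(d)))
  grid <- seq(-span, span, length.out = grid_points)
  dx <- grid[2L] - grid[1L]
  # likelihood matrix L[n, k] = p(d_n | b = grid_k)
  act <- which(!degenerate)
  L <- matrix(0, n, grid_points)
  for (i in act) {
    z <- (d[i] - grid) / scale[i]
    L[i, ] <- if (likelihood == "t")
      stats::dt(z, df = b$n_ens - 1L) / scale[i]
    else stats::dnorm(z) / scale[i]
  }
  if (any(degenerate)) {
    for (i in which(degenerate))   # point mass at the observed residual
      L[i, which.min(abs(grid - d[i]))] <- 1 / dx
  }
  prior <- stats::density(d, from = -span, to = span, n = grid_points)$y
  prior <- prior / (sum(prior) * dx)
  iterations <- 0L
  l1_trace <- numeric(0)
  post <- NULL
  repeat {
    post <- L * matrix(prior, n, grid_points, byrow = TRUE)
    norm <- rowSums(post) * dx
    post <- post / norm
    if (iterations >= max_iter) break
    new_prior <- colMeans(post)
    new_prior <- new_prior / (sum(new_prior) * dx)
    l1 <- sum(abs(new_prior - prior)) * dx
    l1_trace <- c(l1_trace, l1)
    prior <- new_prior
    iterations <- iterations + 1L
    if (l1 < tol) {
      post <- L * matrix(prior, n, grid_points, byrow = TRUE)
      post <- post / (rowSums(post) * dx)
      break
    }
  }
  enb <- as.numeric(post %*% abs(grid)) * dx    # E|b_n|
  per <- data.frame(residual = d, nonvariance = enb,
                    variance = abs(d) - enb)
  new_decomposition(per, iterations = iterations, prior = prior,
                    grid = grid, l1_trace = l1_trace)
}

new_decomposition <- function(per, iterations, prior, grid, l1_trace) {
  structure(list(per_point = per,
                 mean_nonvariance = mean(per$nonvariance),
                 mean_variance = mean(per$variance),
                 mae = mean(abs(per$residual)),
                 iterations = iterations, prior = prior, grid = grid,
                 l1_trace = l1_trace),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf(paste0("<decomposition: MAE %.4g = nonvariance %.4g + ",
                     "variance %.4g (%d iterations)>\n"),
              x$mae, x$mean_nonvariance, x$mean_variance, x$iterations))
  invisible(x)
}

#' Fraction of the ensemble error not caused by variance
#'
#' Dataset-mean nonvariance error divided by the ensemble MAE. On noise-free
#' data this is the bias fraction.
#'
#' @param r a `decomposition_result`.
#' @return a scalar fraction.
#' @export
nonvariance_fraction <- function(r) {
  stopifnot(inherits(r, "decomposition_result"))
  if (r$mae <= 0) stop("nonvariance fraction is undefined at zero MAE")
  r$mean_nonvariance / r$mae
}
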