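# calibration curves, AUCE, uncertainty rescaling, sharpness / dispersion

test_that("coverage matches a well-specified simulation and is monotone", {
  set.seed(8)
  n <- 10000
  mu <- rnorm(n, sd = 10)
  sig <- 1.5
  y <- mu + rnorm(n, sd = sig)  # targets drawn from the assumed normal
  crv <- calibration_curve(mu, rep(sig, n), y, p_grid = seq(0.05, 0.95, 0.05),
                           quantile = "normal")
  expect_true(all(abs(crv$curve$coverage - crv$curve$p) < 0.02))
  expect_true(all(diff(crv$curve$coverage) >= 0))
  # all-zero stds with off-target predictions: coverage 0 everywhere
  crv0 <- calibration_curve(mu + 1, rep(0, n), y, quantile = "normal")
  expect_true(all(crv0$curve$coverage == 0))
  expect_error(calibration_curve(numeric(0), numeric(0), numeric(0)),
               "at least one")
  expect_error(calibration_curve(mu, rep(sig, n), y, quantile = "t"),
               "n_ens")
})

test_that("AUCE closed forms hold exactly", {
  grid <- seq(0.01, 0.99, by = 0.01)
  mk <- function(cov) structure(list(curve = data.frame(p = grid,
                                                        coverage = cov),
                                     n_test = 1L, convention = "t/s"),
                                class = "calibration_curve")
  expect_equal(auce(mk(grid)), 0, tolerance = 1e-3)     # perfect calibration
  expect_equal(auce(mk(rep(0, 99))), 0.5)               # integral of p
  expect_equal(auce(mk(rep(1, 99))), 0.5)               # integral of 1 - p
})

test_that("well-specified ensembles calibrate; bias destroys calibration", {
  set.seed(9)
  n <- 10000; nens <- 20; sig <- 1.5
  mu <- rnorm(n, sd = 10)
  P <- matrix(rnorm(nens * n, sd = sig), nens, n) +
    matrix(mu, nens, n, byrow = TRUE)
  y <- mu + rnorm(n, sd = sig)
  blk <- ensemble_block(P, y)
  crv <- calibration_curve(ensemble_mean(blk), ensemble_std(blk), y,
                           n_ens = nens)
  expect_lt(auce(crv), 0.03)
  # constant bias of 3 sigma on all predictions
  crv_b <- calibration_curve(ensemble_mean(blk) + 3 * sig, ensemble_std(blk),
                             y, n_ens = nens)
  expect_gt(auce(crv_b), 0.3)
})

test_that("uncertainty rescaling preserves ratios and hits the reference mean", {
  expect_equal(scale_uncertainty(c(1, 1), 5), c(5, 5))
  u <- c(0.5, 2, 4)
  out <- scale_uncertainty(u, 3)
  expect_equal(mean(out), 3)
  expect_equal(out / u, rep(3 / mean(u), 3))
  expect_error(scale_uncertainty(c(0, 0), 1), "non-positive")
})

test_that("sharpness and dispersion summarize the uncertainty vector", {
  sd0 <- sharpness_dispersion(c(2, 20))
  expect_equal(sd0$sharpness, 11)
  expect_equal(sharpness_dispersion(rep(3, 10))$dispersion, 0)
  u <- c(1, 2, 5, 9)
  expect_equal(sharpness_dispersion(u)$dispersion,
               sharpness_dispersion(10 * u)$dispersion)  # scale invariance
  expect_error(sharpness_dispersion(numeric(0)), "empty")
  expect_error(sharpness_dispersion(c(0, 0)), "undefined")
})
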