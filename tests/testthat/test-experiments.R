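# scripted studies: shapes of the output tables, determinism, and the
# noise-free degenerate case

test_that("learning curves have one row per size and mode and are deterministic", {
  world <- small_world()
  lc <- run_learning_curve(world, sizes = c(500, 2000), sigma = 1, seed = 4)
  expect_equal(nrow(lc), 6L)
  expect_setequal(unique(lc$mode), c("clean/clean", "noisy/clean",
                                     "noisy/noisy"))
  lc2 <- run_learning_curve(world, sizes = c(500, 2000), sigma = 1, seed = 4)
  expect_identical(lc, lc2)
  expect_false(is.null(attr(lc, "config")))
})

test_that("without noise the three learning-curve modes coincide", {
  world <- small_world()
  lc <- run_learning_curve(world, sizes = 2000, sigma = 0, seed = 4)
  expect_lt(diff(range(lc$rmse)), 1e-9)
})

test_that("the noise-shape table covers every distribution and size", {
  world <- small_world()
  ns <- run_noise_shape_study(world, sizes = c(1000, 4000), sigma = 1,
                              seed = 5)
  expect_equal(nrow(ns), 8L)
  expect_setequal(unique(ns$distribution),
                  c("gaussian", "uniform", "hyperbolic", "bimodal"))
  expect_true(is.numeric(attr(ns, "max_gap")))
})

test_that("the systematic-noise table has two regimes by two methods", {
  world <- small_world()
  out <- run_systematic_noise_study(
    world, n_train = 3000, rule = regime_element("N", 20, 2),
    cfg = surrogate_config("atom_net", aggregation = "norm", mve = TRUE,
                           epochs = 30, lr = 3e-3),
    n_ens = 2, seed = 6)
  expect_equal(nrow(out), 4L)
  expect_setequal(paste(out$regime, out$method),
                  c("high mve", "low mve", "high ensemble_scaled",
                    "low ensemble_scaled"))
  expect_true(all(out$mean_uncertainty > 0))
})

test_that("bias-variance rows satisfy the additivity identity", {
  world <- small_world()
  bv <- run_bias_variance_study(world, sizes = c(500, 2000),
                                hidden_sizes = 16,
                                cfg = surrogate_config("atom_net",
                                                       aggregation = "norm",
                                                       epochs = 20,
                                                       lr = 3e-3),
                                n_ens = 3, n_test_cap = 500, seed = 7)
  expect_equal(nrow(bv), 2L)
  expect_equal(bv$nonvariance + bv$variance, bv$mae_ensemble,
               tolerance = 1e-8)
  expect_equal(bv$fraction, bv$nonvariance / bv$mae_ensemble)
})

test_that("ensemble sweeps report nested prefix ensembles", {
  world <- small_world()
  sw <- run_ensemble_sweep(world,
                           scenarios = list(
                             a = list(n_train = 1000,
                                      cfg = surrogate_config(
                                        "atom_net", aggregation = "norm",
                                        hidden_size = 16, epochs = 15,
                                        lr = 3e-3))),
                           max_ens = 3, reps = 2, n_test_cap = 400, seed = 8)
  expect_equal(nrow(sw), 6L)
  expect_equal(sort(unique(sw$n_ens)), 1:3)
})

test_that("leakage study: zero leakage means perceived equals true", {
  world <- small_world()
  lk <- run_leakage_study(world, leak_fractions = c(0, 1),
                          n_molecules = 600,
                          cfg = surrogate_config("fp_ffnn", hidden_size = 32,
                                                 fp_nbits = 256, epochs = 15),
                          seed = 9)
  expect_identical(lk$perceived_mae[1L], lk$true_mae[1L])
  expect_true(is.na(lk$true_mae[2L]))   # every test record leaked
  errs <- attr(lk, "errors")
  expect_true(all(c("abs_error", "leaked") %in% names(errs)))
})

test_that("extrapolation study reports both buckets per aggregation and size", {
  world <- small_world()
  ex <- run_extrapolation_study(world, sizes = c(1000, 3000),
                                cfg = surrogate_config("atom_net",
                                                       hidden_size = 32,
                                                       epochs = 25,
                                                       lr = 3e-3),
                                seed = 10)
  expect_equal(nrow(ex), 8L)
  expect_setequal(unique(ex$bucket), c("large", "small"))
  pm <- attr(ex, "per_molecule")
  expect_true(all(pm$heavy_atoms >= 1))
})
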