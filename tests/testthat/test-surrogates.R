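# surrogate regressors: exact-capacity ridge, fingerprint net, atom net,
# mean-variance estimation, ensembles

train_ready <- function(n = 5000, seed = 21) {
  world <- small_world()
  ds <- split_dataset(world$dataset, 0.1, 0.8, seed = seed)
  adduq:::subsample_trainval(ds, n, seed = seed + 1L)
}

test_set <- function(ds) subset_dataset(ds, which(ds$split == "test"))

test_that("group_linear learns the exactly linear target to numerical precision", {
  ds <- train_ready(5000)
  m <- train_surrogate(ds, surrogate_config("group_linear"))
  test <- test_set(ds)
  p <- predict(m, test)
  expect_lt(sqrt(mean((p$mean - test$target)^2)), 1e-3)
  # linearity: ethane prediction is twice the CH3 coefficient
  gl_coef <- m$fit$coef[match("C;H3;1C", m$vocab)]
  expect_equal(predict(m, list(parse_smiles("CC")))$mean, 2 * gl_coef,
               tolerance = 1e-9)
})

test_that("out-of-vocabulary groups contribute zero and are flagged", {
  ds <- train_ready(2000)
  m <- train_surrogate(ds, surrogate_config("group_linear"))
  # a molecule certain to be outside the fitted vocabulary: plain methane
  # is in domain, but a corrupted vocab test needs a fresh key; use F2CO-like
  probe <- list(parse_smiles("C"), parse_smiles("FC(F)(F)C(F)(F)F"))
  p <- predict(m, probe)
  known <- vapply(probe,
                  function(g) all(extract_groups(g) %in% m$vocab), logical(1))
  expect_identical(p$oov, !known)
  if (any(p$oov)) expect_true(all(is.finite(p$mean)))
})

test_that("tiny fingerprints collide for many distinct molecules", {
  world <- small_world()
  mols <- world$dataset$molecules[1:500]
  fps <- vapply(mols, circular_fingerprint, integer(10), radius = 2L,
                nbits = 10L)
  expect_gt(sum(duplicated(t(fps))), 0)
})

test_that("MVE recovers the homoscedastic noise level", {
  ds <- train_ready(6000)
  noisy <- apply_noise(ds, noise_spec("gaussian", 1, seed = 3))
  cfg <- surrogate_config("atom_net", aggregation = "norm", mve = TRUE,
                          epochs = 80, warmup_frac = 0.15, lr = 3e-3)
  m <- train_surrogate(noisy, cfg)
  p <- predict(m, test_set(noisy))
  expect_true(all(p$std > 0))
  expect_gt(mean(p$std), 0.85)
  expect_lt(mean(p$std), 1.15)
})

test_that("training and prediction are deterministic given the seed", {
  ds <- train_ready(1500)
  cfg <- surrogate_config("atom_net", aggregation = "norm", epochs = 10,
                          lr = 3e-3, init_seed = 5)
  m1 <- train_surrogate(ds, cfg)
  m2 <- train_surrogate(ds, cfg)
  test <- test_set(ds)
  expect_identical(predict(m1, test)$mean, predict(m2, test)$mean)
  expect_identical(predict(m1, test)$mean, predict(m1, test)$mean)
})

test_that("ensembles share splits and differ only by initialization seed", {
  ds <- train_ready(1500)
  cfg <- surrogate_config("atom_net", aggregation = "norm", epochs = 10,
                          lr = 3e-3)
  e1 <- train_ensemble(ds, cfg, n_ens = 3, base_seed = 7)
  e2 <- train_ensemble(ds, cfg, n_ens = 3, base_seed = 7)
  test <- test_set(ds)
  P1 <- predict_matrix(e1, test)
  expect_identical(P1, predict_matrix(e2, test))
  expect_equal(dim(P1), c(3L, length(test)))
  expect_identical(vapply(e1, function(m) m$cfg$init_seed, integer(1)),
                   7:9)
  # n_ens = 1 equals a single training run at the base seed
  cfg1 <- cfg
  cfg1$init_seed <- 7L
  single <- train_surrogate(ds, cfg1)
  expect_equal(predict_matrix(train_ensemble(ds, cfg, 1, base_seed = 7),
                              test)[1L, ],
               predict(single, test)$mean)
})

test_that("the convex group_linear ensemble has zero spread", {
  ds <- train_ready(1500)
  ens <- train_ensemble(ds, surrogate_config("group_linear"), n_ens = 3,
                        base_seed = 1)
  P <- predict_matrix(ens, test_set(ds))
  expect_lt(max(apply(P, 2, sd)), 1e-12)
})

test_that("mean aggregation compresses size information that sum retains", {
  ds <- train_ready(5000)
  chains <- lapply(2:9, function(k)
    parse_smiles(paste(rep("C", k), collapse = "")))
  tg <- vapply(chains, additive_target, numeric(1), gm = small_world()$gm)
  preds <- lapply(c("mean", "sum"), function(aggr) {
    cfg <- surrogate_config("atom_net", aggregation = aggr, epochs = 60,
                            lr = 3e-3)
    predict(train_surrogate(ds, cfg), chains)$mean
  })
  expect_lt(sd(preds[[1L]]), 0.8 * sd(tg))   # mean: compressed
  expect_gt(sd(preds[[2L]]), 0.9 * sd(tg))   # sum: tracks the extensive target
})

test_that("corrupted element features degrade accuracy", {
  ds <- train_ready(4000)
  test <- test_set(ds)
  worse <- vapply(1:5, function(s) {
    c0 <- surrogate_config("atom_net", aggregation = "norm", epochs = 30,
                           lr = 3e-3, init_seed = s)
    cc <- c0
    cc$element_map <- c(N = "C")
    r0 <- sqrt(mean((predict(train_surrogate(ds, c0), test)$mean -
                       test$target)^2))
    rc <- sqrt(mean((predict(train_surrogate(ds, cc), test)$mean -
                       test$target)^2))
    rc > r0
  }, logical(1))
  expect_gte(sum(worse), 4)
})

test_that("the selected epoch has the lowest validation loss", {
  ds <- train_ready(1500)
  m <- train_surrogate(ds, surrogate_config("atom_net", aggregation = "norm",
                                            epochs = 25, lr = 3e-3))
  log <- m$fit$log
  expect_equal(m$fit$selected_epoch, log$epoch[which.min(log$val_loss)])
  expect_lte(min(log$val_loss), log$val_loss[nrow(log)])
})

test_that("invalid configurations are rejected", {
  expect_error(surrogate_config("atom_net", aggregation = "norm",
                                norm_constant = 0), "norm_constant")
  expect_error(surrogate_config("group_linear", mve = TRUE), "not available")
  expect_error(surrogate_config("fp_ffnn", hidden_size = 0), "hidden_size")
})
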