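# Scripted, seeded reproductions of the controlled experiments: learning
# curves under random noise, noise-shape equivalence, systematic noise with
# mean-variance estimation, bias/variance decomposition across data and
# model sizes, ensembling sweeps, calibration, size extrapolation, and
# deliberate data leakage. Every function takes a master seed and returns a
# tidy data.frame with the resolved configuration attached as an attribute.

default_test_frac <- 0.1

# reassign train/val inside the non-test records: N records at `ratio`
subsample_trainval <- function(ds, N, seed, ratio = 0.8) {
  nontest <- which(ds$split != "test")
  if (N > length(nontest))
    stop("requested training size ", N, " exceeds the available pool of ",
         length(nontest))
  with_seed(seed, {
    pick <- sample(nontest, N)
    ntr <- round(ratio * N)
    split <- ds$split
    split[nontest] <- "unused"
    split[pick[seq_len(ntr)]] <- "train"
    split[pick[(ntr + 1L):N]] <- "val"
    ds$split <- split
    ds
  })
}

eval_rmse <- function(pred, y) sqrt(mean((pred - y)^2))
eval_mae <- function(pred, y) mean(abs(pred - y))

finish_table <- function(df, config) {
  attr(df, "config") <- config
  rownames(df) <- NULL
  df
}

#' Learning curves under random noise
#'
#' Trains one surrogate per training size on clean targets and one on noisy
#' targets, and evaluates the test RMSE in the three modes `clean/clean`
#' (clean training, clean test), `noisy/clean` (noisy training, clean test:
#' the true model performance) and `noisy/noisy` (noisy training, noisy
#' test: the perceived performance, which plateaus at the noise standard
#' deviation - the aleatoric limit).
#'
#' @param world a [synthetic_world()].
#' @param sizes training-set sizes (train + validation records).
#' @param sigma noise standard deviation, kcal/mol.
#' @param distribution noise shape, see [noise_spec()].
#' @param cfg surrogate configuration (default: the exact-capacity
#'   group-count ridge surrogate).
#' @param seed master seed.
#' @return data.frame with columns `n`, `mode`, `rmse`.
#' @export
run_learning_curve <- function(world, sizes = c(500, 2000, 8000, 32000),
                               sigma = 1, distribution = "gaussian",
                               cfg = surrogate_config("group_linear"),
                               seed = 1L) {
  ds <- split_dataset(world$dataset, default_test_frac, 0.8,
                      "record_random", seed = seed)
  noisy <- apply_noise(ds, noise_spec(distribution, sigma,
                                      apply_to = c("train", "val", "test"),
                                      seed = seed + 1L))
  itest <- split_idx(ds, "test")
  test <- subset_dataset(ds, itest)
  y_clean <- test$target
  y_noisy <- noisy$noisy_target[itest]
  rows <- list()
  for (N in sizes) {
    dsN <- subsample_trainval(noisy, N, seed = seed + 2L + N)
    clean_ds <- dsN
    clean_ds$noisy_target <- NULL                # train on clean targets
    m_clean <- train_surrogate(clean_ds, cfg)
    m_noisy <- train_surrogate(dsN, cfg)
    p_clean <- predict(m_clean, test)$mean
    p_noisy <- predict(m_noisy, test)$mean
    rows[[length(rows) + 1L]] <- data.frame(
      n = N,
      mode = c("clean/clean", "noisy/clean", "noisy/noisy"),
      rmse = c(eval_rmse(p_clean, y_clean), eval_rmse(p_noisy, y_clean),
               eval_rmse(p_noisy, y_noisy)))
  }
  finish_table(do.call(rbind, rows),
               list(sizes = sizes, sigma = sigma,
                    distribution = distribution, seed = seed, cfg = cfg))
}

#' Noise-shape equivalence study
#'
#' Learning curves with noise of equal mean (0) and standard deviation but
#' different shapes applied to both the training and test targets. The
#' summary attribute `max_gap` is the largest pairwise RMSE difference
#' between distributions at the largest size.
#'
#' @inheritParams run_learning_curve
#' @param distributions noise shapes to compare.
#' @return data.frame with columns `distribution`, `n`, `rmse`.
#' @export
run_noise_shape_study <- function(world, sizes = c(2000, 8000, 20000),
                                  sigma = 1,
                                  distributions = c("gaussian", "uniform",
                                                    "hyperbolic", "bimodal"),
                                  cfg = surrogate_config("group_linear"),
                                  seed = 1L) {
  rows <- list()
  for (dist in distributions) {
    lc <- run_learning_curve(world, sizes = sizes, sigma = sigma,
                             distribution = dist, cfg = cfg, seed = seed)
    lc <- lc[lc$mode == "noisy/noisy", c("n", "rmse")]
    rows[[dist]] <- cbind(distribution = dist, lc)
  }
  out <- do.call(rbind, rows)
  at_max <- out$rmse[out$n == max(sizes)]
  out <- finish_table(out, list(sizes = sizes, sigma = sigma,
                                distributions = distributions, seed = seed))
  attr(out, "max_gap") <- max(at_max) - min(at_max)
  out
}

#' Systematic (regime-dependent) noise with mean-variance estimation
#'
#' Applies Gaussian noise whose standard deviation depends on a regime rule
#' (element containment or target sign) to train, validation and test
#' targets, trains a mean-variance estimation surrogate and a point-model
#' ensemble on the noisy data, and reports per-regime RMSE and mean
#' predicted uncertainty. The ensemble spread is rescaled so its test-set
#' average matches the MVE average ([scale_uncertainty()]) before comparing
#' regimes.
#'
#' @param world a [synthetic_world()].
#' @param n_train training + validation records.
#' @param rule a regime rule ([regime_element()] or [regime_sign()]).
#' @param cfg MVE surrogate configuration (`mve = TRUE` enforced).
#' @param n_ens point-model ensemble size.
#' @param cfg_ensemble optional configuration for the point-model ensemble
#'   (default: `cfg` without MVE, capped at 40 epochs).
#' @param seed master seed.
#' @return data.frame with columns `regime` (`high`/`low` noise), `method`
#'   (`mve` / `ensemble_scaled`), `rmse`, `mean_uncertainty`.
#' @export
run_systematic_noise_study <- function(world, n_train = 20000L,
                                       rule = regime_element("N", 20, 2),
                                       cfg = surrogate_config(
                                         "atom_net", aggregation = "norm",
                                         mve = TRUE, epochs = 150L,
                                         warmup_frac = 0.15, lr = 3e-3),
                                       n_ens = 5L, cfg_ensemble = NULL,
                                       seed = 1L) {
  cfg$mve <- TRUE
  ds <- split_dataset(world$dataset, default_test_frac, 0.8,
                      "record_random", seed = seed)
  noisy <- apply_noise(ds, noise_spec("gaussian", regime = rule,
                                      apply_to = c("train", "val", "test"),
                                      seed = seed + 1L))
  dsN <- subsample_trainval(noisy, n_train, seed = seed + 2L)
  itest <- split_idx(dsN, "test")
  test <- subset_dataset(dsN, itest)
  y_test <- test$noisy_target
  hi <- test$regime == "high"
  mve_model <- train_surrogate(dsN, cfg)
  mve_pred <- predict(mve_model, test)
  cfg_pt <- cfg_ensemble %||% {
    tmp <- cfg
    tmp$epochs <- min(cfg$epochs, 40L)  # point models converge much earlier
    tmp
  }
  cfg_pt$mve <- FALSE
  ens <- train_ensemble(dsN, cfg_pt, n_ens = n_ens, base_seed = seed + 10L)
  blk <- ensemble_block(predict_matrix(ens, test), y_test)
  ens_mean <- ensemble_mean(blk)
  ens_unc <- scale_uncertainty(ensemble_std(blk), mean(mve_pred$std))
  per_regime <- function(sel, pred, unc) {
    c(rmse = eval_rmse(pred[sel], y_test[sel]),
      mean_uncertainty = mean(unc[sel]))
  }
  out <- rbind(
    data.frame(regime = "high", method = "mve",
               t(per_regime(hi, mve_pred$mean, mve_pred$std))),
    data.frame(regime = "low", method = "mve",
               t(per_regime(!hi, mve_pred$mean, mve_pred$std))),
    data.frame(regime = "high", method = "ensemble_scaled",
               t(per_regime(hi, ens_mean, ens_unc))),
    data.frame(regime = "low", method = "ensemble_scaled",
               t(per_regime(!hi, ens_mean, ens_unc))))
  finish_table(out, list(n_train = n_train, rule = rule, n_ens = n_ens,
                         seed = seed, cfg = cfg))
}

#' Bias / variance decomposition across data and model sizes
#'
#' Trains surrogate ensembles over a grid of training sizes and hidden sizes
#' on the noise-free targets, applies [infer_decomposition()] on the test
#' set and reports the error contributions. On this noiseless data the
#' nonvariance error is the bias error.
#'
#' @param world a [synthetic_world()].
#' @param sizes training sizes.
#' @param hidden_sizes hidden layer widths.
#' @param cfg base surrogate configuration.
#' @param n_ens ensemble size used for the inference.
#' @param n_test_cap optional cap on test records used in the inference.
#' @param seed master seed.
#' @return data.frame with columns `n`, `hidden`, `mae_single`,
#'   `mae_ensemble`, `nonvariance`, `variance`, `fraction`.
#' @export
run_bias_variance_study <- function(world, sizes = c(500, 2000, 8000),
                                    hidden_sizes = c(8, 32, 128),
                                    cfg = surrogate_config("atom_net",
                                                           aggregation = "norm",
                                                           epochs = 40L,
                                                           lr = 3e-3),
                                    n_ens = 5L, n_test_cap = 2000L,
                                    seed = 1L) {
  ds <- split_dataset(world$dataset, default_test_frac, 0.8,
                      "record_random", seed = seed)
  itest <- split_idx(ds, "test")
  if (length(itest) > n_test_cap)
    itest <- with_seed(seed, sample(itest, n_test_cap))
  test <- subset_dataset(ds, itest)
  rows <- list()
  for (N in sizes) {
    dsN <- subsample_trainval(ds, N, seed = seed + N)
    for (h in hidden_sizes) {
      cfg_h <- cfg
      cfg_h$hidden_size <- as.integer(h)
      ens <- train_ensemble(dsN, cfg_h, n_ens = n_ens,
                            base_seed = seed + 100L)
      blk <- ensemble_block(predict_matrix(ens, test), test$target)
      dec <- infer_decomposition(blk)
      rows[[length(rows) + 1L]] <- data.frame(
        n = N, hidden = h,
        mae_single = eval_mae(blk$predictions[1L, ], test$target),
        mae_ensemble = dec$mae,
        nonvariance = dec$mean_nonvariance,
        variance = dec$mean_variance,
        fraction = nonvariance_fraction(dec))
    }
  }
  finish_table(do.call(rbind, rows),
               list(sizes = sizes, hidden_sizes = hidden_sizes,
                    n_ens = n_ens, seed = seed, cfg = cfg))
}

#' Ensemble-size sweep
#'
#' For each scenario, trains a pool of `max_ens` submodels and evaluates the
#' test MAE of nested prefix ensembles of size 1..`max_ens`, repeated
#' `reps` times with different subsample and initialization seeds.
#'
#' @param world a [synthetic_world()].
#' @param scenarios named list; each element is a list with components
#'   `n_train`, `cfg`, and optional `sigma` (training noise).
#' @param max_ens largest ensemble size.
#' @param reps seeded repetitions.
#' @param n_test_cap cap on test records.
#' @param seed master seed.
#' @return data.frame with columns `scenario`, `rep`, `n_ens`, `mae`.
#' @export
run_ensemble_sweep <- function(world,
                               scenarios = list(
                                 base = list(n_train = 2000L,
                                             cfg = surrogate_config(
                                               "atom_net",
                                               aggregation = "norm",
                                               hidden_size = 32L,
                                               epochs = 30L, lr = 3e-3))),
                               max_ens = 8L, reps = 5L, n_test_cap = 2000L,
                               seed = 1L) {
  ds0 <- split_dataset(world$dataset, default_test_frac, 0.8,
                       "record_random", seed = seed)
  itest <- split_idx(ds0, "test")
  if (length(itest) > n_test_cap)
    itest <- with_seed(seed, sample(itest, n_test_cap))
  test <- subset_dataset(ds0, itest)
  rows <- list()
  for (sc in names(scenarios)) {
    spec <- scenarios[[sc]]
    sigma <- spec$sigma %||% 0
    for (r in seq_len(reps)) {
      ds <- ds0
      if (sigma > 0)
        ds <- apply_noise(ds, noise_spec("gaussian", sigma,
                                         apply_to = c("train", "val"),
                                         seed = seed + 31L * r))
      dsN <- subsample_trainval(ds, spec$n_train, seed = seed + 7L * r)
      ens <- train_ensemble(dsN, spec$cfg, n_ens = max_ens,
                            base_seed = seed + 1000L * r)
      P <- predict_matrix(ens, test)
      for (k in seq_len(max_ens)) {
        blk <- ensemble_block(P[seq_len(k), , drop = FALSE], test$target)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, rep = r, n_ens = k,
          mae = ensemble_errors(blk)$mae)
      }
    }
  }
  finish_table(do.call(rbind, rows),
               list(scenarios = scenarios, max_ens = max_ens, reps = reps,
                    seed = seed))
}

#' Calibration study
#'
#' Computes confidence-based calibration curves and AUCE for ensembles
#' trained under the given scenarios (varying training size, hidden size, or
#' training noise). Test targets include the injected noise when a scenario
#' adds noise to the test split.
#'
#' @param world a [synthetic_world()].
#' @param scenarios named list, elements with `n_train`, `cfg`, optional
#'   `sigma` (noise on all splits).
#' @param n_ens ensemble size.
#' @param n_test_cap cap on test records.
#' @param seed master seed.
#' @return data.frame with columns `scenario`, `auce`; per-scenario curves
#'   in `attr(, "curves")`.
#' @export
run_calibration_study <- function(world,
                                  scenarios = list(
                                    good = list(n_train = 8000L,
                                                cfg = surrogate_config(
                                                  "atom_net",
                                                  aggregation = "norm",
                                                  hidden_size = 64L,
                                                  epochs = 40L, lr = 3e-3)),
                                    tiny = list(n_train = 500L,
                                                cfg = surrogate_config(
                                                  "atom_net",
                                                  aggregation = "norm",
                                                  hidden_size = 64L,
                                                  epochs = 40L, lr = 3e-3))),
                                  n_ens = 5L, n_test_cap = 2000L, seed = 1L) {
  ds0 <- split_dataset(world$dataset, default_test_frac, 0.8,
                       "record_random", seed = seed)
  itest <- split_idx(ds0, "test")
  if (length(itest) > n_test_cap)
    itest <- with_seed(seed, sample(itest, n_test_cap))
  curves <- list()
  rows <- list()
  for (sc in names(scenarios)) {
    spec <- scenarios[[sc]]
    sigma <- spec$sigma %||% 0
    ds <- ds0
    if (sigma > 0)
      ds <- apply_noise(ds, noise_spec("gaussian", sigma,
                                       apply_to = c("train", "val", "test"),
                                       seed = seed + 17L))
    test <- subset_dataset(ds, itest)
    y <- if (sigma > 0) test$noisy_target else test$target
    dsN <- subsample_trainval(ds, spec$n_train, seed = seed + 3L)
    ens <- train_ensemble(dsN, spec$cfg, n_ens = n_ens,
                          base_seed = seed + 100L)
    blk <- ensemble_block(predict_matrix(ens, test), y)
    crv <- calibration_curve(ensemble_mean(blk), ensemble_std(blk), y,
                             n_ens = n_ens, quantile = "t")
    curves[[sc]] <- crv
    rows[[length(rows) + 1L]] <- data.frame(scenario = sc, auce = auce(crv))
  }
  out <- finish_table(do.call(rbind, rows),
                      list(scenarios = scenarios, n_ens = n_ens, seed = seed))
  attr(out, "curves") <- curves
  out
}

#' Size-extrapolation study (sum vs mean aggregation)
#'
#' Trains the atom-contribution surrogate only on molecules in the larger
#' heavy-atom bucket and evaluates both buckets, contrasting sum and mean
#' aggregation on the extensive target. Also returns per-molecule absolute
#' errors against molecule size at the largest training size.
#'
#' @param world a [synthetic_world()].
#' @param sizes training sizes (within the large bucket).
#' @param bucket_split molecules with more heavy atoms than this are the
#'   training bucket.
#' @param aggregations aggregation functions to compare.
#' @param cfg base atom_net configuration (aggregation overridden).
#' @param seed master seed.
#' @return data.frame with columns `aggregation`, `bucket`, `n`, `mae`;
#'   per-molecule errors in `attr(, "per_molecule")`.
#' @export
run_extrapolation_study <- function(world, sizes = c(2000, 8000, 20000),
                                    bucket_split = 6L,
                                    aggregations = c("mean", "sum"),
                                    cfg = surrogate_config("atom_net",
                                                           hidden_size = 64L,
                                                           epochs = 60L,
                                                           lr = 3e-3),
                                    seed = 1L) {
  natoms <- vapply(world$dataset$molecules, function(g) length(g$element),
                   numeric(1))
  big <- which(natoms > bucket_split)
  small <- which(natoms <= bucket_split)
  if (!length(big) || !length(small))
    stop("both heavy-atom buckets must be populated")
  ds_big <- split_dataset(subset_dataset(world$dataset, big),
                          default_test_frac, 0.8, "record_random",
                          seed = seed)
  test_big <- subset_dataset(ds_big, split_idx(ds_big, "test"))
  test_small <- subset_dataset(world$dataset, small)
  rows <- list()
  per_mol <- list()
  for (aggr in aggregations) {
    cfg_a <- cfg
    cfg_a$aggregation <- aggr
    for (N in sizes) {
      dsN <- subsample_trainval(ds_big, N, seed = seed + N)
      m <- train_surrogate(dsN, cfg_a)
      p_big <- predict(m, test_big)$mean
      p_small <- predict(m, test_small)$mean
      rows[[length(rows) + 1L]] <- data.frame(
        aggregation = aggr,
        bucket = c("large", "small"),
        n = N,
        mae = c(eval_mae(p_big, test_big$target),
                eval_mae(p_small, test_small$target)))
      if (N == max(sizes)) {
        per_mol[[aggr]] <- data.frame(
          aggregation = aggr,
          heavy_atoms = c(vapply(test_big$molecules,
                                 function(g) length(g$element), numeric(1)),
                          vapply(test_small$molecules,
                                 function(g) length(g$element), numeric(1))),
          abs_error = abs(c(p_big - test_big$target,
                            p_small - test_small$target)))
      }
    }
  }
  out <- finish_table(do.call(rbind, rows),
                      list(sizes = sizes, bucket_split = bucket_split,
                           aggregations = aggregations, seed = seed,
                           cfg = cfg))
  attr(out, "per_molecule") <- do.call(rbind, per_mol)
  out
}

#' Data-leakage study on the two-temperature dataset
#'
#' Builds the internal-energy dataset U(T) at two temperatures, contaminates
#' the test split at each leak fraction ([contaminate_split()]), trains the
#' fingerprint surrogate with the temperature as an input, and reports the
#' perceived test MAE (all test records, leaked included) against the true
#' MAE (non-leaked records only).
#'
#' @param world a [synthetic_world()].
#' @param leak_fractions fractions of test records whose other-temperature
#'   sibling is forced into training.
#' @param n_molecules molecules drawn from the pool (two records each).
#' @param cfg surrogate configuration (needs the temperature input, so
#'   `fp_ffnn`).
#' @param seed master seed.
#' @return data.frame with columns `leak_fraction`, `perceived_mae`,
#'   `true_mae`; per-record errors with leak flags in `attr(, "errors")`.
#' @export
run_leakage_study <- function(world, leak_fractions = c(0, 0.25, 0.5, 0.75, 1),
                              n_molecules = 4000L,
                              cfg = surrogate_config("fp_ffnn",
                                                     hidden_size = 64L,
                                                     epochs = 40L),
                              seed = 1L) {
  mols <- with_seed(seed,
                    sample(world$dataset$molecules,
                           min(n_molecules, length(world$dataset$molecules))))
  gm_cp <- derive_cp_model(world$gm, seed = seed + 1L)
  tds <- make_temperature_dataset(world$gm, gm_cp, mols)
  rows <- list()
  errs <- list()
  for (f in leak_fractions) {
    ds <- contaminate_split(tds, f, seed = seed + 2L)
    m <- train_surrogate(ds, cfg)
    itest <- split_idx(ds, "test")
    test <- subset_dataset(ds, itest)
    err <- abs(predict(m, test)$mean - test$target)
    leaked <- test$leaked
    rows[[length(rows) + 1L]] <- data.frame(
      leak_fraction = f,
      perceived_mae = mean(err),
      true_mae = if (any(!leaked)) mean(err[!leaked]) else NA_real_)
    errs[[length(errs) + 1L]] <- data.frame(leak_fraction = f,
                                            abs_error = err,
                                            leaked = leaked)
  }
  out <- finish_table(do.call(rbind, rows),
                      list(leak_fractions = leak_fractions,
                           n_molecules = n_molecules, seed = seed,
                           cfg = cfg))
  attr(out, "errors") <- do.call(rbind, errs)
  out
}
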