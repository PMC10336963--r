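# the group-additivity world: coefficient fitting, exact targets, noise,
# splits, temperature datasets and deliberate leakage

test_that("ridge fit recovers known coefficients on a full-rank design", {
  # two groups only: methane (pure c1) and ethane (2 x c2)
  mols <- c(lapply(1:1, function(i) parse_smiles("C")),
            list(parse_smiles("CC"), parse_smiles("CCC")))
  truth <- c("C;H4;" = -17.9, "C;H3;1C" = -10.0, "C;H2;1C+1C" = -5.0)
  ref <- make_dataset(rep(mols, 40), group_model(truth))
  gm <- fit_group_coefficients(ref, ridge_penalty = 1e-8, min_count = 1,
                               rounding = 10)
  # closed-form least squares oracle
  G <- as.matrix(group_count_matrix(ref$molecules))
  oracle <- solve(crossprod(G) + 1e-8 * diag(3), crossprod(G, ref$target))
  expect_equal(unname(gm$coefficients[colnames(G)]), unname(drop(oracle)),
               tolerance = 1e-8)
  expect_equal(gm$coefficients[names(truth)], truth, tolerance = 1e-6)
})

test_that("min-count filter drops rare groups and their molecules", {
  mols <- c(rep(list(parse_smiles("CC")), 5), list(parse_smiles("CCO")))
  truth <- c("C;H3;1C" = -10, "C;H2;1C+1O" = 3, "O;H1;1C" = -40)
  ref <- make_dataset(mols, group_model(truth))
  gm <- fit_group_coefficients(ref, min_count = 2, rounding = 6)
  expect_false("C;H2;1C+1O" %in% names(gm$coefficients))
  expect_false("O;H1;1C" %in% names(gm$coefficients))
  expect_equal(unname(gm$coefficients["C;H3;1C"]), -10, tolerance = 1e-5)
  expect_error(fit_group_coefficients(ref, min_count = 100), "fit error")
})

test_that("the ridge limit drives coefficients to zero", {
  mols <- rep(list(parse_smiles("CC"), parse_smiles("CCC")), 60)
  ref <- make_dataset(mols, group_model(c("C;H3;1C" = -10, "C;H2;1C+1C" = -5)))
  gm <- fit_group_coefficients(ref, ridge_penalty = 1e12, min_count = 1,
                               rounding = 6)
  expect_true(all(abs(gm$coefficients) < 1e-3))
})

test_that("additive targets are exact sums and respect the domain", {
  gm <- group_model(c("C;H3;1C" = -10.0, "C;H4;" = -17.9))
  expect_identical(additive_target(parse_smiles("CC"), gm), -20.0)
  expect_identical(additive_target(parse_smiles("C"), gm), -17.9)
  expect_error(additive_target(parse_smiles("CCO"), gm), "domain error")

  mols <- list(parse_smiles("C"), parse_smiles("CCO"), parse_smiles("CC"),
               parse_smiles("OCO"), parse_smiles("CCC"))
  kept <- filter_in_domain(mols, gm)
  expect_length(kept, 2L)  # methane and ethane; propane has an interior CH2
  expect_identical(write_smiles(kept[[1L]]), write_smiles(mols[[1L]]))
  expect_length(filter_in_domain(list(), gm), 0L)
})

test_that("synthetic targets equal the group-model sum bit-identically", {
  world <- small_world()
  idx <- seq(1, length(world$dataset), by = 97)
  for (i in idx)
    expect_identical(world$dataset$target[i],
                     additive_target(world$dataset$molecules[[i]], world$gm))
})

test_that("molecule generation is deterministic, unique and valence-valid", {
  m1 <- generate_molecules(500, 6, seed = 7)
  m2 <- generate_molecules(500, 6, seed = 7)
  expect_identical(vapply(m1, write_smiles, character(1)),
                   vapply(m2, write_smiles, character(1)))
  expect_false(anyDuplicated(vapply(m1, write_smiles, character(1))) > 0)
  expect_true(all(vapply(m1, function(g) length(g$element), numeric(1)) <= 6))
  for (g in m1[seq(1, 500, by = 25)]) expect_silent(validate_molgraph(g))
  # only one molecule exists with a single carbon
  expect_identical(write_smiles(generate_molecules(1, 1, "C", seed = 1)[[1L]]),
                   "C")
  # asking for more unique molecules than exist reports the achievable count
  expect_error(generate_molecules(10, 1, "C", seed = 1), "1 of 10")
})

test_that("noise draws have the configured moments for every shape", {
  n <- 1e5
  for (dist in c("gaussian", "uniform", "hyperbolic", "bimodal")) {
    x <- with(list(), {
      set.seed(31)
      adduq:::draw_unit_noise(n, dist)
    })
    expect_lt(abs(mean(x)), 0.02)
    expect_true(abs(sd(x) - 1) < 0.02,
                label = paste(dist, "std within 2% of sigma"))
  }
  set.seed(1)
  u <- adduq:::draw_unit_noise(n, "uniform")
  expect_true(all(abs(u) <= sqrt(3)))
  expect_error(adduq:::draw_unit_noise(10, "cauchy"), "config error")
  expect_error(noise_spec("cauchy"), "config error")
})

test_that("apply_noise respects sigma, splits and regime rules", {
  world <- small_world()
  ds <- split_dataset(subset_dataset(world$dataset, 1:2000), 0.1, 0.8,
                      seed = 3)
  z <- apply_noise(ds, noise_spec("gaussian", 0, seed = 1))
  expect_identical(z$noisy_target, z$target)

  z <- apply_noise(ds, noise_spec("gaussian", 1, apply_to = "train",
                                  seed = 1))
  expect_identical(z$noisy_target[z$split != "train"],
                   z$target[z$split != "train"])
  expect_false(any(z$noisy_target[z$split == "train"] ==
                     z$target[z$split == "train"]))
  # reproducible
  z2 <- apply_noise(ds, noise_spec("gaussian", 1, apply_to = "train",
                                   seed = 1))
  expect_identical(z$noisy_target, z2$noisy_target)

  # element regime: high sigma on N-containing molecules
  zr <- apply_noise(ds, noise_spec("gaussian",
                                   regime = regime_element("N", 20, 2),
                                   seed = 2))
  hasN <- vapply(ds$molecules, function(g) "N" %in% g$element, logical(1))
  expect_identical(zr$regime, ifelse(hasN, "high", "low"))
  resid <- zr$noisy_target - zr$target
  expect_gt(sd(resid[hasN]), 10)
  expect_lt(sd(resid[!hasN]), 4)
  # sign regime labels by clean target sign
  zs <- apply_noise(ds, noise_spec("gaussian", regime = regime_sign(20, 2),
                                   seed = 2))
  expect_identical(zs$regime, ifelse(ds$target > 0, "high", "low"))
})

test_that("split sizes, grouping and determinism follow the configuration", {
  world <- small_world()
  ds <- subset_dataset(world$dataset, 1:100)
  s <- split_dataset(ds, 0.1, 0.8, seed = 5)
  expect_equal(as.vector(table(s$split)[c("train", "val", "test")]),
               c(72, 18, 10))
  s2 <- split_dataset(ds, 0.1, 0.8, seed = 5)
  expect_identical(s$split, s2$split)

  # grouped: both temperature records of a molecule share the split
  cp <- derive_cp_model(world$gm, seed = 1)
  tds <- make_temperature_dataset(world$gm, cp, ds$molecules[1:60])
  g <- split_dataset(tds, 0.2, 0.8, mode = "molecule_grouped", seed = 2)
  per_mol <- tapply(g$split, g$smiles, function(x) length(unique(x)))
  expect_true(all(per_mol == 1L))
})

test_that("temperature datasets are linear in T with two records per molecule", {
  world <- small_world()
  mols <- world$dataset$molecules[1:50]
  cp <- derive_cp_model(world$gm, seed = 4)
  expect_true(all(cp$coefficients >= 0.005 & cp$coefficients <= 0.02))
  tds <- make_temperature_dataset(world$gm, cp, mols)
  expect_length(tds, 100L)
  h <- make_dataset(mols, world$gm)$target
  cpv <- make_dataset(mols, cp)$target
  at0 <- tds$temperature == 0
  expect_equal(tds$target[at0], h)                     # U(0) = H
  expect_equal(tds$target[!at0] - tds$target[at0], 298 * cpv)
})

test_that("contamination forces the configured fraction of siblings into train", {
  world <- small_world()
  mols <- world$dataset$molecules[1:400]
  cp <- derive_cp_model(world$gm, seed = 4)
  tds <- make_temperature_dataset(world$gm, cp, mols)
  for (f in c(0, 0.5, 1)) {
    ds <- contaminate_split(tds, f, seed = 9)
    itest <- which(ds$split == "test")
    leaked <- ds$leaked[itest]
    expect_equal(sum(leaked), round(f * length(itest)))
    train_smiles <- unique(ds$smiles[ds$split == "train"])
    in_train <- ds$smiles[itest] %in% train_smiles
    expect_identical(in_train, as.logical(leaked))
  }
})
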