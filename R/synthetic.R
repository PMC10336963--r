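# The noise-free group-additivity world: molecule generation, coefficient
# fitting, exact additive targets, controlled noise injection, and splits
# (including deliberate train/test contamination).

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# molecule generation

#' Generate random valence-valid molecules
#'
#' Seeded random growth over the supported elements: atoms are attached one
#' by one to atoms with free valence (bond orders weighted toward single
#' bonds), with occasional ring closures between non-adjacent atoms. The
#' result is deduplicated by canonical SMILES, emulating a GDB-like pool of
#' small C/N/O/F molecules at desk scale.
#'
#' @param n number of unique molecules requested.
#' @param max_heavy_atoms maximum number of heavy atoms per molecule.
#' @param elements subset of `c("C","N","O","F")`.
#' @param seed integer seed; the output is reproducible.
#' @param ring_prob probability of attempting each of two ring-closure draws
#'   per molecule.
#' @return list of [molgraph()] objects, all valence-valid, connected and
#'   pairwise non-isomorphic.
#' @export
generate_molecules <- function(n, max_heavy_atoms, elements = c("C", "N", "O", "F"),
                               seed = 1L, ring_prob = 0.35) {
  stopifnot(n >= 1L, max_heavy_atoms >= 1L)
  elements <- match.arg(elements, several.ok = TRUE)
  with_seed(seed, {
    el_prob <- c(C = 0.55, N = 0.17, O = 0.17, F = 0.11)[elements]
    el_prob <- el_prob / sum(el_prob)
    size_prob <- 1.4^seq_len(max_heavy_atoms)
    size_prob <- size_prob / sum(size_prob)
    raw <- generate_pool_cpp(as.integer(n), as.integer(max_heavy_atoms),
                             match(elements, names(VALENCE)) - 1L,
                             el_prob, size_prob, ring_prob,
                             max(60L * n, 2000L))
    lapply(raw, function(r) {
      g <- structure(list(element = names(VALENCE)[r$element + 1L],
                          hcount = r$hcount,
                          bond_i = r$bonds[, 1L], bond_j = r$bonds[, 2L],
                          bond_order = r$bonds[, 3L]),
                     class = "molgraph")
      attr(g, "smiles") <- r$smiles
      g
    })
  })
}

# ---------------------------------------------------------------------------
# group models

#' Group-additivity model
#'
#' A map from canonical 1-bond-radius group keys (see [extract_groups()]) to
#' additive coefficients in kcal/mol. Acts as the exact ground-truth property
#' function of the synthetic world.
#'
#' @param coefficients named numeric vector, names are group keys.
#' @param min_count minimum reference occurrence count used in fitting.
#' @param rounding decimal places the coefficients are rounded to.
#' @return an object of class `group_model`.
#' @export
group_model <- function(coefficients, min_count = NA_integer_, rounding = 3L) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  structure(list(coefficients = coefficients,
                 min_count = min_count, rounding = rounding),
            class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("<group_model: %d groups, rounded to %d decimals>\n",
              length(x$coefficients), x$rounding))
  invisible(x)
}

#' Group-count design matrix
#'
#' Sparse matrix of group occurrence counts, one row per molecule, one column
#' per group key.
#'
#' @param mols list of [molgraph()].
#' @param vocab optional fixed column vocabulary (character vector of group
#'   keys); groups outside it are dropped (callers can detect that via
#'   [filter_in_domain()]).
#' @return a `dgCMatrix` with `colnames` set to the group keys.
#' @export
group_count_matrix <- function(mols, vocab = NULL) {
  keys <- lapply(mols, extract_groups)
  lens <- lengths(keys)
  all_keys <- unlist(keys, use.names = FALSE)
  if (is.null(vocab)) vocab <- sort(unique(all_keys))
  j <- match(all_keys, vocab)
  i <- rep.int(seq_along(mols), lens)
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                       dims = c(length(mols), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Fit group-additivity coefficients by ridge regression
#'
#' Groups occurring fewer than `min_count` times in the reference are
#' dropped, together with every reference molecule containing a dropped
#' group; the coefficients then minimize \eqn{\|Gc - y\|^2 + \lambda\|c\|^2}
#' on the retained design and are rounded to `rounding` decimals.
#'
#' @param reference a [property_dataset()] with clean targets.
#' @param ridge_penalty nonnegative ridge penalty \eqn{\lambda}.
#' @param min_count minimum total occurrence count for a group to be kept.
#' @param rounding decimal places for the fitted coefficients.
#' @return a [group_model()].
#' @export
fit_group_coefficients <- function(reference, ridge_penalty = 1e-6,
                                   min_count = 100L, rounding = 3L) {
  stopifnot(inherits(reference, "property_dataset"), ridge_penalty >= 0)
  G <- group_count_matrix(reference$molecules)
  y <- reference$target
  counts <- Matrix::colSums(G)
  keep <- counts >= min_count
  if (!any(keep)) stop("fit error: no group occurs at least ", min_count,
                       " times; design is empty after filtering")
  dropped <- G[, !keep, drop = FALSE]
  rows <- if (ncol(dropped)) Matrix::rowSums(dropped) == 0 else
    rep(TRUE, nrow(G))
  G <- G[rows, keep, drop = FALSE]
  y <- y[rows]
  if (!nrow(G)) stop("fit error: no molecule is made up entirely of retained groups")
  A <- Matrix::crossprod(G) + Matrix::Diagonal(ncol(G), ridge_penalty)
  coef <- as.numeric(Matrix::solve(A, Matrix::crossprod(G, y)))
  names(coef) <- colnames(G)
  group_model(round(coef, rounding), min_count = min_count,
              rounding = rounding)
}

#' Exact additive target of a molecule
#'
#' Sum of the group-model coefficients over [extract_groups()]. Errors if any
#' group of the molecule is missing from the model (out of domain).
#'
#' @param g a [molgraph()].
#' @param gm a [group_model()].
#' @return the target value in kcal/mol.
#' @export
additive_target <- function(g, gm) {
  additive_target_keys(extract_groups(g), gm)
}

# shared by additive_target and make_dataset so both sum the coefficients in
# atom order: generated targets are bit-identical to additive_target()
additive_target_keys <- function(keys, gm) {
  m <- match(keys, names(gm$coefficients))
  if (anyNA(m))
    stop("domain error: group key not in model: ", keys[which(is.na(m))[1L]])
  sum(gm$coefficients[m])
}

#' Keep only molecules fully covered by a group model
#'
#' @param mols list of [molgraph()].
#' @param gm a [group_model()].
#' @return the order-preserving subset of `mols` whose every group key has a
#'   coefficient in `gm`.
#' @export
filter_in_domain <- function(mols, gm) {
  known <- names(gm$coefficients)
  mols[vapply(mols, function(g) all(extract_groups(g) %in% known),
              logical(1))]
}

# ---------------------------------------------------------------------------
# property datasets

#' Property dataset
#'
#' The experiment substrate: molecules with clean (exact additive) targets,
#' optional noisy targets, optional auxiliary temperature input, regime
#' labels, split assignments and leakage flags. Stored column-wise; use
#' `as.data.frame()` for a tidy view (molecules rendered as SMILES).
#'
#' @param molecules list of [molgraph()].
#' @param target numeric clean targets, kcal/mol.
#' @param noisy_target optional numeric noisy targets.
#' @param temperature optional numeric auxiliary input (K).
#' @param regime optional character regime labels.
#' @param split optional character split assignment
#'   (`"train"/"val"/"test"`).
#' @param leaked optional logical leakage flag for test records.
#' @param smiles optional canonical SMILES (computed if missing).
#' @return an object of class `property_dataset`.
#' @export
property_dataset <- function(molecules, target, noisy_target = NULL,
                             temperature = NULL, regime = NULL, split = NULL,
                             leaked = NULL, smiles = NULL) {
  n <- length(molecules)
  stopifnot(length(target) == n)
  if (is.null(smiles))
    smiles <- vapply(molecules, canonical_smiles, character(1))
  for (v in list(noisy_target, temperature, regime, split, leaked))
    if (!is.null(v)) stopifnot(length(v) == n)
  structure(list(molecules = molecules, smiles = smiles,
                 target = as.numeric(target),
                 noisy_target = noisy_target, temperature = temperature,
                 regime = regime, split = split, leaked = leaked),
            class = "property_dataset")
}

#' @export
length.property_dataset <- function(x) length(x$molecules)

#' @export
print.property_dataset <- function(x, ...) {
  cat(sprintf("<property_dataset: %d records%s%s%s>\n", length(x),
              if (!is.null(x$noisy_target)) ", noisy targets" else "",
              if (!is.null(x$temperature)) ", temperature input" else "",
              if (!is.null(x$split))
                sprintf(", split %s", paste(names(table(x$split)),
                                            table(x$split), sep = ":",
                                            collapse = "/")) else ""))
  invisible(x)
}

#' @export
as.data.frame.property_dataset <- function(x, ...) {
  df <- data.frame(smiles = x$smiles, target = x$target,
                   stringsAsFactors = FALSE)
  for (col in c("noisy_target", "temperature", "regime", "split", "leaked"))
    if (!is.null(x[[col]])) df[[col]] <- x[[col]]
  df
}

#' Subset a property dataset by record index
#'
#' @param ds a [property_dataset()].
#' @param idx integer or logical index.
#' @export
subset_dataset <- function(ds, idx) {
  out <- ds
  out$molecules <- ds$molecules[idx]
  out$smiles <- ds$smiles[idx]
  for (col in c("target", "noisy_target", "temperature", "regime", "split",
                "leaked"))
    if (!is.null(ds[[col]])) out[[col]] <- ds[[col]][idx]
  out
}

#' Build a dataset of exact additive targets
#'
#' @param mols list of in-domain [molgraph()].
#' @param gm a [group_model()].
#' @return a [property_dataset()] whose `target` equals the group-model sum
#'   exactly.
#' @export
make_dataset <- function(mols, gm) {
  y <- vapply(seq_along(mols), function(i) {
    tryCatch(additive_target_keys(extract_groups(mols[[i]]), gm),
             error = function(e)
               stop("domain error: molecule ", i, ": ",
                    conditionMessage(e), call. = FALSE))
  }, numeric(1))
  property_dataset(mols, y)
}

# ---------------------------------------------------------------------------
# noise

#' Noise specification
#'
#' All four distributions are parameterized to mean 0 and standard deviation
#' `sigma`: `gaussian` is N(0, sigma^2); `uniform` is uniform on
#' (-sqrt(3) sigma, sqrt(3) sigma); `hyperbolic` is the hyperbolic-secant
#' density scaled to std sigma; `bimodal` is an equal mixture of
#' N(+0.9 sigma, 0.19 sigma^2) and N(-0.9 sigma, 0.19 sigma^2).
#'
#' @param distribution one of `"gaussian"`, `"uniform"`, `"hyperbolic"`,
#'   `"bimodal"`.
#' @param sigma noise standard deviation, kcal/mol.
#' @param apply_to splits that receive noise; records in other splits keep
#'   their clean values.
#' @param regime optional regime rule created by [regime_element()] or
#'   [regime_sign()]; when given, `sigma` is ignored and the rule's
#'   `sigma_hi`/`sigma_lo` apply per record.
#' @param seed integer seed for the noise draw.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(distribution = c("gaussian", "uniform", "hyperbolic",
                                        "bimodal"),
                       sigma = 1, apply_to = c("train", "val", "test"),
                       regime = NULL, seed = 1L) {
  if (is.character(distribution) &&
      !all(distribution[1L] %in% c("gaussian", "uniform", "hyperbolic",
                                   "bimodal")))
    stop("config error: unknown noise distribution '", distribution[1L], "'")
  distribution <- match.arg(distribution)
  stopifnot(sigma >= 0, all(apply_to %in% c("train", "val", "test")))
  structure(list(distribution = distribution, sigma = sigma,
                 apply_to = apply_to, regime = regime, seed = seed),
            class = "noise_spec")
}

#' @describeIn noise_spec regime rule keyed on element containment: records
#'   whose molecule contains `element` get `sigma_hi`, others `sigma_lo`.
#' @param element element symbol for [regime_element()].
#' @param sigma_hi,sigma_lo per-regime noise standard deviations.
#' @export
regime_element <- function(element = "N", sigma_hi = 20, sigma_lo = 2) {
  structure(list(type = "element", element = element,
                 sigma_hi = sigma_hi, sigma_lo = sigma_lo),
            class = "regime_rule")
}

#' @describeIn noise_spec regime rule keyed on the sign of the clean target:
#'   positive targets get `sigma_hi`, negative (and zero) get `sigma_lo`.
#' @export
regime_sign <- function(sigma_hi = 20, sigma_lo = 2) {
  structure(list(type = "sign", sigma_hi = sigma_hi, sigma_lo = sigma_lo),
            class = "regime_rule")
}

regime_is_high <- function(rule, ds) {
  switch(rule$type,
         element = vapply(ds$molecules,
                          function(g) rule$element %in% g$element, logical(1)),
         sign = ds$target > 0,
         stop("config error: unknown regime rule type '", rule$type, "'"))
}

# zero-mean, unit-sd draws from the named shape
draw_unit_noise <- function(n, distribution) {
  switch(distribution,
         gaussian = stats::rnorm(n),
         uniform = stats::runif(n, -sqrt(3), sqrt(3)),
         # hyperbolic secant: quantile transform, variance 1
         hyperbolic = (2 / pi) * log(tan(pi * stats::runif(n) / 2)),
         bimodal = sample(c(-1, 1), n, replace = TRUE) * 0.9 +
           stats::rnorm(n, sd = sqrt(1 - 0.81)),
         stop("config error: unknown noise distribution '", distribution, "'"))
}

#' Inject noise into a dataset
#'
#' Adds a zero-mean draw of the configured shape and standard deviation to
#' the clean target of every record whose split is in `spec$apply_to`;
#' other records keep their clean values in `noisy_target`. With a regime
#' rule, each record's sigma is `sigma_hi` or `sigma_lo` according to the
#' rule, and the regime label (`"high"`/`"low"`) is stored.
#'
#' @param ds a [property_dataset()] with clean targets.
#' @param spec a [noise_spec()].
#' @return the dataset with `noisy_target` (and possibly `regime`) set.
#' @export
apply_noise <- function(ds, spec) {
  stopifnot(inherits(ds, "property_dataset"), inherits(spec, "noise_spec"))
  n <- length(ds)
  sel <- if (is.null(ds$split)) rep(TRUE, n) else ds$split %in% spec$apply_to
  sigma <- rep(spec$sigma, n)
  if (!is.null(spec$regime)) {
    hi <- regime_is_high(spec$regime, ds)
    sigma <- ifelse(hi, spec$regime$sigma_hi, spec$regime$sigma_lo)
    ds$regime <- ifelse(hi, "high", "low")
  }
  eps <- with_seed(spec$seed, draw_unit_noise(n, spec$distribution)) * sigma
  ds$noisy_target <- ds$target + ifelse(sel, eps, 0)
  ds
}

# ---------------------------------------------------------------------------
# splitting

#' Assign train/val/test splits
#'
#' `record_random` assigns records independently; `molecule_grouped` keeps
#' all records sharing a molecule (e.g. the two temperatures of a
#' temperature dataset) in the same split. Split sizes follow
#' `round(test_frac * n)` for the test set and `train_val_ratio` within the
#' remainder.
#'
#' @param ds a [property_dataset()].
#' @param test_frac fraction of records held out for testing, in (0,1).
#' @param train_val_ratio train share of the non-test records, in (0,1).
#' @param mode `"record_random"` or `"molecule_grouped"`.
#' @param seed integer seed.
#' @return the dataset with `split` set.
#' @export
split_dataset <- function(ds, test_frac = 0.1, train_val_ratio = 0.8,
                          mode = c("record_random", "molecule_grouped"),
                          seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1,
            train_val_ratio > 0, train_val_ratio < 1)
  mode <- match.arg(mode)
  n <- length(ds)
  n_test <- round(test_frac * n)
  n_train <- round(train_val_ratio * (n - n_test))
  with_seed(seed, {
    split <- character(n)
    if (mode == "record_random") {
      ord <- sample.int(n)
      split[ord[seq_len(n_train)]] <- "train"
      split[ord[n_train + seq_len(n - n_test - n_train)]] <- "val"
      split[ord[(n - n_test + 1L):n]] <- "test"
    } else {
      groups <- split(seq_len(n), ds$smiles)
      gsize <- lengths(groups)
      if (max(gsize) > min(n_test, n_train, n - n_test - n_train))
        stop("grouped mode: a molecule group is larger than a split")
      groups <- groups[sample.int(length(groups))]
      # whole groups are dealt to each split until its quota is reached
      csum <- cumsum(lengths(groups))
      n_test_g <- which(csum >= n_test)[1L]
      n_val_g <- which(csum - csum[n_test_g] >= n - n_test - n_train)[1L]
      role <- rep("train", length(groups))
      role[seq_len(n_test_g)] <- "test"
      role[(n_test_g + 1L):n_val_g] <- "val"
      for (k in seq_along(groups)) split[groups[[k]]] <- role[k]
    }
    ds$split <- split
    ds
  })
}

# ---------------------------------------------------------------------------
# temperature datasets and deliberate leakage

#' Derive a heat-capacity group model
#'
#' Draws one Cp coefficient per group of `gm_H` from a seeded
#' uniform(0.005, 0.02) kcal/mol/K, giving a linear-in-temperature
#' group-additive internal energy U(T) = H + Cp * T.
#'
#' @param gm_H enthalpy [group_model()].
#' @param seed integer seed.
#' @param range lower/upper bound of the uniform draw.
#' @return a Cp [group_model()] over the same group vocabulary.
#' @export
derive_cp_model <- function(gm_H, seed = 1L, range = c(0.005, 0.02)) {
  keys <- names(gm_H$coefficients)
  cp <- with_seed(seed, stats::runif(length(keys), range[1L], range[2L]))
  names(cp) <- keys
  group_model(round(cp, 6L), min_count = gm_H$min_count, rounding = 6L)
}

#' Two-temperature internal-energy dataset
#'
#' Two records per molecule with target U(T) = H(mol) + Cp(mol) * T, where H
#' and Cp are both group-additive, and the temperature stored as an auxiliary
#' input. The substrate of the data-leakage experiments.
#'
#' @param gm_H,gm_Cp enthalpy and heat-capacity [group_model()]s.
#' @param mols list of molecules, in-domain for both models.
#' @param temperatures numeric vector of temperatures (K), default `c(0, 298)`.
#' @return a [property_dataset()] with `2 * length(mols)` records.
#' @export
make_temperature_dataset <- function(gm_H, gm_Cp, mols,
                                     temperatures = c(0, 298)) {
  H <- make_dataset(mols, gm_H)$target
  Cp <- make_dataset(mols, gm_Cp)$target
  nt <- length(temperatures)
  idx <- rep(seq_along(mols), each = nt)
  tt <- rep(temperatures, times = length(mols))
  property_dataset(mols[idx], target = H[idx] + Cp[idx] * tt,
                   temperature = tt,
                   smiles = vapply(mols, canonical_smiles, character(1))[idx])
}

#' Contaminate a two-temperature split with deliberate leakage
#'
#' Starts from a molecule-grouped split of a [make_temperature_dataset()]
#' dataset and keeps one record (a random temperature) per test molecule in
#' the test set. For `round(leak_fraction * n_test)` of the test molecules
#' the other-temperature sibling record is forced into the training set
#' (leaked); the siblings of clean test molecules are excluded entirely
#' (split `"unused"`). Each test record is flagged in `leaked`.
#'
#' @param ds a dataset built by [make_temperature_dataset()].
#' @param leak_fraction fraction of test records to contaminate, in `[0,1]`.
#' @param seed integer seed.
#' @param test_frac,train_val_ratio split parameters, as in
#'   [split_dataset()].
#' @return the dataset with `split` and `leaked` set.
#' @export
contaminate_split <- function(ds, leak_fraction, seed = 1L, test_frac = 0.1,
                              train_val_ratio = 0.8) {
  stopifnot(leak_fraction >= 0, leak_fraction <= 1,
            !is.null(ds$temperature))
  with_seed(seed, {
    groups <- split(seq_len(length(ds)), ds$smiles)
    stopifnot(all(lengths(groups) == 2L))
    ng <- length(groups)
    n_test <- round(test_frac * ng)
    n_train <- round(train_val_ratio * (ng - n_test))
    ord <- sample.int(ng)
    role <- character(ng)
    role[ord[seq_len(n_train)]] <- "train"
    role[ord[n_train + seq_len(ng - n_test - n_train)]] <- "val"
    role[ord[(ng - n_test + 1L):ng]] <- "test"
    split <- character(length(ds))
    leaked <- rep(NA, length(ds))
    test_groups <- which(role == "test")
    n_leak <- round(leak_fraction * length(test_groups))
    leak_groups <- test_groups[seq_len(n_leak)]  # ord is already random
    for (k in seq_len(ng)) {
      idx <- groups[[k]]
      if (role[k] != "test") {
        split[idx] <- role[k]
      } else {
        keep <- idx[sample.int(length(idx), 1L)]
        sib <- setdiff(idx, keep)
        split[keep] <- "test"
        if (k %in% leak_groups) {
          split[sib] <- "train"
          leaked[keep] <- TRUE
        } else {
          split[sib] <- "unused"
          leaked[keep] <- FALSE
        }
      }
    }
    ds$split <- split
    ds$leaked <- leaked
    ds
  })
}

# ---------------------------------------------------------------------------
# the assembled synthetic world

#' Build the synthetic group-additivity world
#'
#' Emulates the study's data construction at desk scale: (i) generate a
#' reference pool of molecules and assign "true" group increments drawn once
#' from a seeded uniform(-15, 15) kcal/mol (the magnitude range of
#' Benson-type formation-enthalpy group increments, chosen so that molecule
#' targets straddle zero); (ii) fit group coefficients to the reference
#' targets by ridge regression with a minimum-count filter and thousandth
#' rounding; (iii) generate a larger pool, keep the molecules fully covered
#' by the fitted coefficients, and compute exact additive targets.
#'
#' @param seed master integer seed.
#' @param reference_n size of the reference (coefficient-fitting) pool.
#' @param pool_n size of the main molecule pool before domain filtering.
#' @param max_heavy_atoms maximum heavy atoms per molecule.
#' @param elements supported elements.
#' @param min_count minimum group occurrence count in the reference.
#' @param ridge_penalty ridge penalty for the coefficient fit.
#' @return a list with components `gm` (the fitted [group_model()]), `truth`
#'   (the generating coefficients), `dataset` (a [property_dataset()] of
#'   in-domain pool molecules with exact targets), and `n_dropped` (pool
#'   molecules discarded as out of domain).
#' @export
synthetic_world <- function(seed = 1L, reference_n = 20000L, pool_n = 50000L,
                            max_heavy_atoms = 9L,
                            elements = c("C", "N", "O", "F"),
                            min_count = 100L, ridge_penalty = 1e-6) {
  ref_mols <- generate_molecules(reference_n, max_heavy_atoms, elements,
                                 seed = seed)
  vocab <- sort(unique(unlist(lapply(ref_mols, extract_groups))))
  truth <- with_seed(seed + 1000L,
                     round(stats::runif(length(vocab), -15, 15), 3L))
  names(truth) <- vocab
  truth_gm <- group_model(truth)
  reference <- make_dataset(ref_mols, truth_gm)
  gm <- fit_group_coefficients(reference, ridge_penalty = ridge_penalty,
                               min_count = min_count)
  pool <- generate_molecules(pool_n, max_heavy_atoms, elements,
                             seed = seed + 2000L)
  pool_in <- filter_in_domain(pool, gm)
  list(gm = gm, truth = truth,
       dataset = make_dataset(pool_in, gm),
       n_dropped = length(pool) - length(pool_in))
}
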