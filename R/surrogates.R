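# Desk-scale surrogate regressors standing in for message-passing networks:
#  * group_linear - ridge regression on exact 1-bond-radius group counts
#    (the model class contains the true additive property, so it is the
#    exact-capacity surrogate),
#  * fp_ffnn     - feed-forward net on a hashed circular fingerprint, with
#    optional mean-variance estimation (two outputs, Gaussian NLL),
#  * atom_net    - the message-passing stand-in: one-hot radius-1 atomic
#    environments aggregated over atoms (sum / mean / norm) into a molecular
#    count vector that feeds a feed-forward readout, with optional MVE
#    heads. The clean target is exactly linear in these counts, so the
#    model class contains the truth.

#' Surrogate model configuration
#'
#' @param model_kind `"group_linear"`, `"fp_ffnn"` or `"atom_net"`.
#' @param hidden_size hidden layer width of the fingerprint net.
#' @param aggregation atom aggregation of `atom_net`: `"sum"`, `"mean"`, or
#'   `"norm"` (sum divided by `norm_constant`, the scaled-sum convention).
#' @param norm_constant divisor for `"norm"` aggregation (default 100).
#' @param fp_radius,fp_nbits circular-fingerprint parameters of `fp_ffnn`.
#' @param fp_counts use counted (`TRUE`, default) or binary fingerprints.
#' @param mve if `TRUE`, train mean-variance estimation: the model outputs a
#'   mean and a variance per record and is trained with the Gaussian
#'   negative log-likelihood (`fp_ffnn` and `atom_net`).
#' @param epochs training epochs; the epoch with the lowest validation loss
#'   is selected.
#' @param warmup_frac fraction of epochs trained on squared error before the
#'   NLL objective is switched on (MVE only).
#' @param batch_size,lr mini-batch size and Adam learning rate.
#' @param init_seed seed controlling initialization and batch order;
#'   ensemble submodels differ only in this seed.
#' @param element_map optional named character vector passed to
#'   [corrupt_elements()]; features are computed on the corrupted view while
#'   targets stay exact.
#' @param ridge_penalty ridge penalty of `group_linear`.
#' @return an object of class `surrogate_config`.
#' @export
surrogate_config <- function(model_kind = c("group_linear", "fp_ffnn",
                                            "atom_net"),
                             hidden_size = 128L,
                             aggregation = c("sum", "mean", "norm"),
                             norm_constant = 100,
                             fp_radius = 2L, fp_nbits = 512L,
                             fp_counts = TRUE,
                             mve = FALSE, epochs = 60L, warmup_frac = 0.25,
                             batch_size = 128L, lr = 1e-3, init_seed = 1L,
                             element_map = NULL, ridge_penalty = 1e-6) {
  model_kind <- match.arg(model_kind)
  aggregation <- match.arg(aggregation)
  stopifnot(hidden_size >= 1L, epochs >= 1L, batch_size >= 1L)
  if (aggregation == "norm" && norm_constant <= 0)
    stop("norm aggregation requires norm_constant > 0")
  if (mve && model_kind == "group_linear")
    stop("mean-variance estimation is not available for group_linear")
  structure(list(model_kind = model_kind, hidden_size = as.integer(hidden_size),
                 aggregation = aggregation, norm_constant = norm_constant,
                 fp_radius = as.integer(fp_radius),
                 fp_nbits = as.integer(fp_nbits), fp_counts = fp_counts,
                 mve = mve, epochs = as.integer(epochs),
                 warmup_frac = warmup_frac,
                 batch_size = as.integer(batch_size), lr = lr,
                 init_seed = as.integer(init_seed), element_map = element_map,
                 ridge_penalty = ridge_penalty),
            class = "surrogate_config")
}

feature_view <- function(mols, cfg) {
  if (is.null(cfg$element_map)) mols
  else lapply(mols, corrupt_elements, element_map = cfg$element_map)
}

# Feature matrix for a set of records. For group_linear / atom_net this is
# the (sparse) environment count matrix over `vocab`; for fp_ffnn a dense
# folded fingerprint matrix, with the temperature appended (scaled by 1/300)
# when the dataset carries one.
featurize_records <- function(mols, cfg, vocab = NULL, temperature = NULL) {
  mols <- feature_view(mols, cfg)
  if (cfg$model_kind == "fp_ffnn") {
    X <- t(vapply(mols, circular_fingerprint, integer(cfg$fp_nbits),
                  radius = cfg$fp_radius, nbits = cfg$fp_nbits,
                  counts = cfg$fp_counts))
    storage.mode(X) <- "double"
    oov <- rep(FALSE, length(mols))
    if (!is.null(temperature)) X <- cbind(X, temperature / 300)
    list(X = X, vocab = NULL, oov = oov)
  } else {
    keys <- lapply(mols, extract_groups)
    if (is.null(vocab)) vocab <- sort(unique(unlist(keys, use.names = FALSE)))
    C <- group_count_matrix(mols, vocab = vocab)
    oov <- as.numeric(Matrix::rowSums(C)) < lengths(keys)
    if (cfg$model_kind == "atom_net") {
      X <- as.matrix(C) / atom_divisor(cfg, mols)
      if (!is.null(temperature)) X <- cbind(X, temperature / 300)
      list(X = X, vocab = vocab, oov = oov)
    } else {
      list(X = C, vocab = vocab, oov = oov)
    }
  }
}

# feature matrix restricted to the (train, val) records, in that order;
# the vocabulary is always derived from the train split alone
training_features <- function(ds, cfg, itr = split_idx(ds, "train"),
                              iva = split_idx(ds, "val")) {
  vocab <- if (cfg$model_kind != "fp_ffnn") {
    mols <- feature_view(ds$molecules[itr], cfg)
    sort(unique(unlist(lapply(mols, extract_groups), use.names = FALSE)))
  } else NULL
  featurize_records(ds$molecules[c(itr, iva)], cfg, vocab = vocab,
                    temperature = ds$temperature[c(itr, iva)])
}

split_idx <- function(ds, which) {
  if (is.null(ds$split)) stop("dataset has no split assignment")
  idx <- which(ds$split == which)
  if (!length(idx)) stop("empty split: ", which)
  idx
}

training_target <- function(ds) ds$noisy_target %||% ds$target

#' Train a surrogate model
#'
#' Trains on the `train` split of `ds` (on noisy targets when present,
#' otherwise clean), uses the `val` split for epoch selection, and is fully
#' deterministic given `cfg$init_seed`.
#'
#' @param ds a [property_dataset()] with `train` and `val` splits.
#' @param cfg a [surrogate_config()].
#' @param features optional precomputed feature object (internal use by
#'   [train_ensemble()]).
#' @return an object of class `trained_surrogate`.
#' @export
train_surrogate <- function(ds, cfg, features = NULL) {
  stopifnot(inherits(ds, "property_dataset"),
            inherits(cfg, "surrogate_config"))
  itr <- split_idx(ds, "train")
  iva <- split_idx(ds, "val")
  y <- training_target(ds)[c(itr, iva)]
  if (!all(is.finite(y))) stop("non-finite training targets")
  if (is.null(features)) features <- training_features(ds, cfg, itr, iva)
  X <- features$X
  stopifnot(nrow(X) == length(itr) + length(iva))
  # local row indices into the (train, val) feature matrix
  itr <- seq_along(itr)
  iva <- length(itr) + seq_along(iva)
  fit <- switch(cfg$model_kind,
    group_linear = {
      G <- X[itr, , drop = FALSE]
      A <- Matrix::crossprod(G) +
        Matrix::Diagonal(ncol(G), cfg$ridge_penalty)
      coef <- as.numeric(Matrix::solve(A, Matrix::crossprod(G, y[itr])))
      val_rmse <- sqrt(mean((as.numeric(X[iva, , drop = FALSE] %*% coef) -
                               y[iva])^2))
      list(coef = coef, selected_epoch = NA_integer_,
           log = data.frame(epoch = NA_integer_, objective = "ridge",
                            val_loss = val_rmse^2))
    },
    atom_net = train_dense_mlp(X, y, itr, iva, cfg),
    fp_ffnn = train_dense_mlp(X, y, itr, iva, cfg))
  structure(list(kind = cfg$model_kind, cfg = cfg, fit = fit,
                 vocab = features$vocab),
            class = "trained_surrogate")
}

atom_divisor <- function(cfg, mols) {
  switch(cfg$aggregation,
         sum = rep(1, length(mols)),
         mean = vapply(mols, function(g) length(g$element), numeric(1)),
         norm = rep(cfg$norm_constant, length(mols)))
}

train_dense_mlp <- function(X, y, itr, iva, cfg) {
  y_center <- mean(y[itr])
  y_scale <- stats::sd(y[itr])
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  yt <- (y - y_center) / y_scale
  warmup <- if (cfg$mve) ceiling(cfg$warmup_frac * cfg$epochs) else 0L
  res <- mlp_train(X[itr, , drop = FALSE], yt[itr],
                   X[iva, , drop = FALSE], yt[iva],
                   hidden = cfg$hidden_size, mve = cfg$mve,
                   epochs = cfg$epochs, warmup = warmup,
                   batch_size = cfg$batch_size, lr = cfg$lr,
                   seed = cfg$init_seed)
  list(params = res$params, y_center = y_center, y_scale = y_scale,
       selected_epoch = res$selected_epoch, log = res$log)
}

#' @export
print.trained_surrogate <- function(x, ...) {
  cat(sprintf("<trained_surrogate: %s%s, selected epoch %s>\n", x$kind,
              if (isTRUE(x$cfg$mve)) " (MVE)" else "",
              x$fit$selected_epoch))
  invisible(x)
}

#' Predict from a trained surrogate
#'
#' @param object a `trained_surrogate`.
#' @param newdata a [property_dataset()] or a list of [molgraph()].
#' @param features optional precomputed feature object (internal).
#' @param ... unused.
#' @return a list with `mean` (numeric vector), `std` (predicted standard
#'   deviation, MVE models only, strictly positive) and `oov` (logical flag
#'   for records containing environments unseen in training; those
#'   contributions are zero).
#' @export
predict.trained_surrogate <- function(object, newdata, features = NULL, ...) {
  if (inherits(newdata, "property_dataset")) {
    mols <- newdata$molecules
    temperature <- newdata$temperature
  } else {
    mols <- newdata
    temperature <- NULL
  }
  if (is.null(features))
    features <- featurize_records(mols, object$cfg, vocab = object$vocab,
                                  temperature = temperature)
  X <- features$X
  out <- switch(object$kind,
    group_linear = list(mean = as.numeric(X %*% object$fit$coef), std = NULL),
    atom_net = ,
    fp_ffnn = {
      fw <- mlp_forward(object$fit$params, X, object$cfg$mve)
      list(mean = fw$mu * object$fit$y_scale + object$fit$y_center,
           std = if (object$cfg$mve) fw$sig * object$fit$y_scale else NULL)
    })
  out$oov <- features$oov
  out
}

#' Train an ensemble of surrogates
#'
#' Submodels share the data split and configuration and differ only in the
#' initialization seed `base_seed + i - 1` (features are computed once and
#' shared).
#'
#' @param ds a [property_dataset()] with splits.
#' @param cfg a [surrogate_config()].
#' @param n_ens ensemble size, `>= 1`.
#' @param base_seed seed of the first submodel.
#' @return list of `trained_surrogate` objects, class `surrogate_ensemble`.
#' @export
train_ensemble <- function(ds, cfg, n_ens = 5L, base_seed = cfg$init_seed) {
  stopifnot(n_ens >= 1L)
  features <- training_features(ds, cfg)
  models <- lapply(seq_len(n_ens), function(i) {
    cfg_i <- cfg
    cfg_i$init_seed <- as.integer(base_seed + i - 1L)
    train_surrogate(ds, cfg_i, features = features)
  })
  structure(models, class = "surrogate_ensemble")
}

#' Ensemble prediction matrix
#'
#' @param ensemble a `surrogate_ensemble`.
#' @param newdata records to predict (see [predict.trained_surrogate()]).
#' @return numeric matrix, rows = submodels, columns = records.
#' @export
predict_matrix <- function(ensemble, newdata) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  if (inherits(newdata, "property_dataset")) {
    mols <- newdata$molecules
    temperature <- newdata$temperature
  } else {
    mols <- newdata
    temperature <- NULL
  }
  features <- featurize_records(mols, ensemble[[1L]]$cfg,
                                vocab = ensemble[[1L]]$vocab,
                                temperature = temperature)
  t(vapply(ensemble,
           function(m) predict(m, newdata, features = features)$mean,
           numeric(length(mols))))
}
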