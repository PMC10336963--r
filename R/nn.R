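# Feed-forward trainer shared by the fingerprint and atom-aggregation
# surrogates: two hidden ReLU layers (the two feed-forward layers of the
# reference architecture), a mean head and (for mean-variance estimation) a
# standard-deviation head trained by Gaussian negative log-likelihood.
# Seeded mini-batch Adam with a fixed step-decay schedule; the epoch with
# the lowest validation loss is kept.

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    state$p[[nm]] <- state$p[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  state
}

# global-norm gradient clipping: guards the NLL phase against the 1/sigma^2
# blow-up on well-fit points (a small predicted sigma otherwise produces
# mean-head gradients large enough to kill the ReLU layers)
clip_grads <- function(g, max_norm = 5) {
  n2 <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
  if (is.finite(n2) && n2 > max_norm) g <- lapply(g, function(x)
    x * (max_norm / n2))
  g
}

adam_init <- function(params) {
  list(p = params,
       m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0)
}

mlp_init <- function(d, h, mve, seed) {
  with_seed(seed, {
    s1 <- sqrt(6 / (d + h))
    s2 <- sqrt(6 / (h + h))
    s3 <- sqrt(6 / (h + 1))
    p <- list(W1 = matrix(stats::runif(d * h, -s1, s1), d, h),
              b1 = numeric(h),
              W2 = matrix(stats::runif(h * h, -s2, s2), h, h),
              b2 = numeric(h),
              Wmu = matrix(stats::runif(h, -s3, s3), h, 1),
              bmu = 0)
    if (mve) {
      p$Ws <- matrix(0, h, 1)
      p$bs <- log(exp(1) - 1)  # softplus^-1(1): initial predicted std of 1
    }
    p
  })
}

mlp_forward <- function(p, X, mve, sd_floor = 1e-3) {
  Z1 <- sweep(X %*% p$W1, 2L, p$b1, "+")
  H1 <- pmax(Z1, 0)
  Z2 <- sweep(H1 %*% p$W2, 2L, p$b2, "+")
  H2 <- pmax(Z2, 0)
  mu <- drop(H2 %*% p$Wmu) + p$bmu
  out <- list(Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, mu = mu)
  if (mve) {
    out$sraw <- drop(H2 %*% p$Ws) + p$bs
    out$sig <- softplus(out$sraw) + sd_floor
  }
  out
}

# loss and parameter gradients for one batch; `nll` switches between squared
# error (mu head only) and the Gaussian negative log-likelihood
mlp_backward <- function(p, X, y, fw, mve, nll) {
  m <- length(y)
  r <- fw$mu - y
  if (nll) {
    iv <- 1 / fw$sig^2
    dmu <- r * iv / m
    dsig <- (1 / fw$sig - r^2 / fw$sig^3) / m
    dsraw <- dsig * stats::plogis(fw$sraw)
  } else {
    dmu <- 2 * r / m
  }
  g <- list(Wmu = crossprod(fw$H2, dmu), bmu = sum(dmu))
  dH2 <- tcrossprod(dmu, p$Wmu[, 1L])
  if (nll) {
    g$Ws <- crossprod(fw$H2, dsraw)
    g$bs <- sum(dsraw)
    dH2 <- dH2 + tcrossprod(dsraw, p$Ws[, 1L])
  } else if (mve) {
    g$Ws <- p$Ws * 0
    g$bs <- 0
  }
  dZ2 <- dH2 * (fw$Z2 > 0)
  g$W2 <- crossprod(fw$H1, dZ2)
  g$b2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(p$W2)
  dZ1 <- dH1 * (fw$Z1 > 0)
  g$W1 <- crossprod(X, dZ1)
  g$b1 <- colSums(dZ1)
  g
}

mlp_loss <- function(p, X, y, mve, nll) {
  fw <- mlp_forward(p, X, mve)
  if (nll) mean(0.5 * log(fw$sig^2) + (y - fw$mu)^2 / (2 * fw$sig^2))
  else mean((y - fw$mu)^2)
}

# train / val matrices and (standardized) targets; returns best-epoch params
# and the per-epoch log
mlp_train <- function(Xtr, ytr, Xval, yval, hidden, mve, epochs, warmup,
                      batch_size, lr, seed) {
  d <- ncol(Xtr)
  st <- adam_init(mlp_init(d, hidden, mve, seed))
  ntr <- nrow(Xtr)
  log <- data.frame(epoch = integer(0), objective = character(0),
                    val_loss = numeric(0))
  best <- list(loss = Inf, p = st$p, epoch = 0L)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      nll <- mve && ep > warmup
      # step decay: refine around the optimum in the last schedule thirds
      lr_ep <- lr * if (ep > 0.85 * epochs) 0.1 else
        if (ep > 0.6 * epochs) 0.3 else 1
      idx <- sample.int(ntr)
      for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
        Xb <- Xtr[b, , drop = FALSE]
        fw <- mlp_forward(st$p, Xb, mve)
        if (!all(is.finite(fw$mu)))
          stop("divergence error at epoch ", ep, ": non-finite predictions")
        g <- clip_grads(mlp_backward(st$p, Xb, ytr[b], fw, mve, nll))
        st <- adam_step(st, g, lr_ep)
      }
      vl <- mlp_loss(st$p, Xval, yval, mve, nll)
      if (!is.finite(vl))
        stop("divergence error at epoch ", ep, ": non-finite validation loss")
      log <- rbind(log, data.frame(epoch = ep,
                                   objective = if (nll) "nll" else "mse",
                                   val_loss = vl))
      # model selection happens on the final objective only
      if ((!mve || nll) && vl < best$loss)
        best <- list(loss = vl, p = st$p, epoch = ep)
    }
  })
  list(params = best$p, selected_epoch = best$epoch, log = log)
}
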