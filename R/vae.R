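# Cluster-aware variational autoencoder, implemented directly on matrix
# operations. The architecture is deliberately small and fixed:
#   encoder:    input(p) -> dense(h) -> batchnorm -> dropout -> [mu_e, sigma_e]
#   decoder:    z(d)     -> dense(h) -> batchnorm -> dropout -> [mu_d, sigma_d]
#   classifier: z(d)     -> batchnorm -> dense(K, softmax)
# Gaussian heads use softplus to keep scales strictly positive. Training is
# Adamax on the mean loss with manual backpropagation (checked against
# numerical gradients in the test suite).

#' Configuration for the cluster-aware VAE
#'
#' @param latent_dim dimension d of the latent representation (default 5).
#' @param hidden_units width of the single hidden layer (default 256).
#' @param dropout_rate dropout probability in encoder/decoder (default 0.3).
#' @param beta weight of the cluster-classifier cross-entropy term in the
#'   loss (default 20000, calibrated against a per-example cross-entropy).
#' @param learning_rate Adamax step size (default 0.001).
#' @param decay_rate multiplicative learning-rate decay applied per epoch
#'   after epoch 3 (default 0.75).
#' @param validation_fraction fraction of rows held out for validation
#'   (default 0.10).
#' @param patience epochs without validation improvement before stopping
#'   (default 20); best weights are restored.
#' @param max_epochs hard cap on epochs (default 500; early stopping
#'   governs in practice).
#' @param batch_size minibatch size (default 128).
#' @param rng_seed integer seed controlling initialization, the train/
#'   validation split, shuffling, dropout and latent sampling.
#' @return a `vae_config` list.
#' @export
vae_config <- function(latent_dim = 5L, hidden_units = 256L,
                       dropout_rate = 0.3, beta = 20000,
                       learning_rate = 0.001, decay_rate = 0.75,
                       validation_fraction = 0.10, patience = 20L,
                       max_epochs = 500L, batch_size = 128L, rng_seed = 1L) {
  stopifnot(latent_dim >= 1L, hidden_units >= 1L,
            dropout_rate > 0, dropout_rate < 1,
            validation_fraction > 0, validation_fraction < 1,
            patience >= 0L, max_epochs >= 1L, batch_size >= 1L)
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate, beta = beta,
                 learning_rate = learning_rate, decay_rate = decay_rate,
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed)),
            class = "vae_config")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

bn_new <- function(width) {
  list(gamma = rep(1, width), beta = rep(0, width),
       rmean = rep(0, width), rvar = rep(1, width))
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99
SOFTPLUS_FLOOR <- 1e-5

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

bn_forward <- function(a, bn, training) {
  if (training) {
    mu <- colMeans(a)
    ac <- sweep(a, 2L, mu, "-")
    v <- colMeans(ac * ac)
    ivar <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(ac, 2L, ivar, "*")
    bn$rmean <- BN_MOMENTUM * bn$rmean + (1 - BN_MOMENTUM) * mu
    bn$rvar <- BN_MOMENTUM * bn$rvar + (1 - BN_MOMENTUM) * v
    cache <- list(xhat = xhat, ivar = ivar, gamma = bn$gamma)
  } else {
    ivar <- 1 / sqrt(bn$rvar + BN_EPS)
    xhat <- sweep(sweep(a, 2L, bn$rmean, "-"), 2L, ivar, "*")
    cache <- NULL
  }
  y <- sweep(sweep(xhat, 2L, bn$gamma, "*"), 2L, bn$beta, "+")
  list(y = y, bn = bn, cache = cache)
}

bn_backward <- function(dy, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, cache$gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(sweep(dxhat, 2L, m1, "-") - sweep(xhat, 2L, m2, "*"),
              2L, cache$ivar, "*")
  list(dx = dx, dgamma = colSums(dy * xhat), dbeta = colSums(dy))
}

#' Build an untrained cluster-aware VAE
#'
#' @param n_features number of input features (genes).
#' @param n_clusters number of cluster labels; when 1 the classifier head is
#'   omitted (the cross-entropy of a single class is uninformative).
#' @param cfg a [vae_config()].
#' @return an untrained model object of class `vae_model`.
#' @export
build_vae <- function(n_features, n_clusters, cfg = vae_config()) {
  stopifnot(n_features >= 1L, n_clusters >= 1L)
  use_classifier <- n_clusters > 1L
  if (!use_classifier) {
    message("single cluster present: classifier head omitted from the VAE loss")
  }
  d <- cfg$latent_dim
  h <- cfg$hidden_units
  p <- as.integer(n_features)
  set.seed(derive_seed(cfg$rng_seed, 11L))
  params <- list(
    W1 = glorot(p, h), b1 = rep(0, h), bn1 = bn_new(h),
    W2 = glorot(h, 2L * d), b2 = rep(0, 2L * d),
    W3 = glorot(d, h), b3 = rep(0, h), bn2 = bn_new(h),
    W4 = glorot(h, 2L * p), b4 = rep(0, 2L * p)
  )
  if (use_classifier) {
    params$bn3 <- bn_new(d)
    params$W5 <- glorot(d, n_clusters)
    params$b5 <- rep(0, n_clusters)
  }
  structure(list(params = params, cfg = cfg, n_features = p,
                 n_clusters = as.integer(n_clusters),
                 use_classifier = use_classifier, trained = FALSE,
                 history = NULL),
            class = "vae_model")
}

# forward pass; training=TRUE draws dropout masks and latent noise from the
# current RNG state and returns all caches needed for backprop
vae_forward <- function(model, x, c_onehot = NULL, training = FALSE) {
  pr <- model$params
  cfg <- model$cfg
  d <- cfg$latent_dim
  p <- model$n_features
  rate <- cfg$dropout_rate
  B <- nrow(x)

  a1 <- sweep(x %*% pr$W1, 2L, pr$b1, "+")
  f1 <- bn_forward(a1, pr$bn1, training)
  if (training) {
    mask1 <- matrix(rbinom(B * ncol(f1$y), 1L, 1 - rate), B) / (1 - rate)
    d1 <- f1$y * mask1
  } else {
    mask1 <- NULL
    d1 <- f1$y
  }
  e2 <- sweep(d1 %*% pr$W2, 2L, pr$b2, "+")
  mu_e <- e2[, seq_len(d), drop = FALSE]
  re <- e2[, d + seq_len(d), drop = FALSE]
  sig_e <- softplus(re) + SOFTPLUS_FLOOR
  if (training) {
    eps <- matrix(rnorm(B * d), B, d)
    z <- mu_e + sig_e * eps
  } else {
    eps <- NULL
    z <- mu_e
  }

  a3 <- sweep(z %*% pr$W3, 2L, pr$b3, "+")
  f3 <- bn_forward(a3, pr$bn2, training)
  if (training) {
    mask3 <- matrix(rbinom(B * ncol(f3$y), 1L, 1 - rate), B) / (1 - rate)
    d3 <- f3$y * mask3
  } else {
    mask3 <- NULL
    d3 <- f3$y
  }
  e4 <- sweep(d3 %*% pr$W4, 2L, pr$b4, "+")
  mu_d <- e4[, seq_len(p), drop = FALSE]
  rd <- e4[, p + seq_len(p), drop = FALSE]
  sig_d <- softplus(rd) + SOFTPLUS_FLOOR

  zeta <- NULL
  fc <- NULL
  if (model$use_classifier) {
    fc <- bn_forward(z, pr$bn3, training)
    logits <- sweep(fc$y %*% pr$W5, 2L, pr$b5, "+")
    lmax <- apply(logits, 1L, max)
    el <- exp(logits - lmax)
    zeta <- el / rowSums(el)
  }
  list(mu_e = mu_e, re = re, sig_e = sig_e, z = z, eps = eps,
       mu_d = mu_d, rd = rd, sig_d = sig_d, zeta = zeta,
       f1 = f1, f3 = f3, fc = fc, d1 = d1, d3 = d3,
       mask1 = mask1, mask3 = mask3)
}

#' Loss terms of the cluster-aware VAE
#'
#' Computes, per example: the Gaussian negative log-likelihood of `x` under
#' the decoder's diagonal Normal, the closed-form KL divergence between the
#' encoder posterior and the standard Normal prior,
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`, and the categorical
#' cross-entropy between the cluster one-hot and the classifier output.
#'
#' @param x input rows (matrix).
#' @param mu_d,sigma_d decoder Normal parameters (same shape as `x`).
#' @param mu_e,sigma_e encoder posterior parameters (rows x d).
#' @param c_onehot cluster one-hot matrix (rows x K), or NULL.
#' @param zeta classifier softmax output (rows x K), or NULL.
#' @return list with per-example vectors `nll`, `kl`, `cce`.
#' @export
vae_loss_terms <- function(x, mu_d, sigma_d, mu_e, sigma_e,
                           c_onehot = NULL, zeta = NULL) {
  nll <- rowSums(0.5 * log(2 * pi) + log(sigma_d) +
                   0.5 * ((x - mu_d) / sigma_d)^2)
  kl <- 0.5 * rowSums(mu_e^2 + sigma_e^2 - 1 - log(sigma_e^2))
  cce <- if (!is.null(zeta) && !is.null(c_onehot)) {
    -rowSums(c_onehot * log(pmax(zeta, 1e-12)))
  } else {
    rep(0, nrow(x))
  }
  list(nll = nll, kl = kl, cce = cce)
}

# scalar loss (mean over rows) given a forward pass
vae_batch_loss <- function(model, x, c_onehot, fw) {
  terms <- vae_loss_terms(x, fw$mu_d, fw$sig_d, fw$mu_e, fw$sig_e,
                          c_onehot, fw$zeta)
  mean(terms$nll) + mean(terms$kl) +
    if (model$use_classifier) model$cfg$beta * mean(terms$cce) else 0
}

# gradients of the mean batch loss w.r.t. every trainable parameter
vae_backward <- function(model, x, c_onehot, fw) {
  pr <- model$params
  cfg <- model$cfg
  B <- nrow(x)
  rate <- cfg$dropout_rate

  g_mu_d <- (fw$mu_d - x) / fw$sig_d^2 / B
  g_sig_d <- (1 / fw$sig_d - (x - fw$mu_d)^2 / fw$sig_d^3) / B
  g_rd <- g_sig_d * stats::plogis(fw$rd)
  g_e4 <- cbind(g_mu_d, g_rd)
  dW4 <- crossprod(fw$d3, g_e4)
  db4 <- colSums(g_e4)
  g_d3 <- tcrossprod(g_e4, pr$W4)
  g_h3 <- g_d3 * fw$mask3
  bb2 <- bn_backward(g_h3, fw$f3$cache)
  dW3 <- crossprod(fw$z, bb2$dx)
  db3 <- colSums(bb2$dx)
  g_z <- tcrossprod(bb2$dx, pr$W3)

  grads <- list(W3 = dW3, b3 = db3,
                bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta),
                W4 = dW4, b4 = db4)

  if (model$use_classifier) {
    g_logits <- cfg$beta * (fw$zeta - c_onehot) / B
    grads$W5 <- crossprod(fw$fc$y, g_logits)
    grads$b5 <- colSums(g_logits)
    g_zb <- tcrossprod(g_logits, pr$W5)
    bb3 <- bn_backward(g_zb, fw$fc$cache)
    grads$bn3 <- list(gamma = bb3$dgamma, beta = bb3$dbeta)
    g_z <- g_z + bb3$dx
  }

  g_mu_e <- g_z + fw$mu_e / B
  g_sig_e <- g_z * fw$eps + (fw$sig_e - 1 / fw$sig_e) / B
  g_re <- g_sig_e * stats::plogis(fw$re)
  g_e2 <- cbind(g_mu_e, g_re)
  grads$W2 <- crossprod(fw$d1, g_e2)
  grads$b2 <- colSums(g_e2)
  g_d1 <- tcrossprod(g_e2, pr$W2)
  g_h1 <- g_d1 * fw$mask1
  bb1 <- bn_backward(g_h1, fw$f1$cache)
  grads$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
  grads$W1 <- crossprod(x, bb1$dx)
  grads$b1 <- colSums(bb1$dx)
  grads
}

adamax_new <- function(params) {
  slot <- function(x) list(m = x * 0, u = x * 0)
  st <- list(t = 0L)
  for (nm in names(params)) {
    if (startsWith(nm, "bn")) {
      st[[nm]] <- list(gamma = slot(params[[nm]]$gamma),
                       beta = slot(params[[nm]]$beta))
    } else {
      st[[nm]] <- slot(params[[nm]])
    }
  }
  st
}

adamax_step <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  corr <- lr / (1 - beta1^state$t)
  upd <- function(theta, g, sl) {
    sl$m <- beta1 * sl$m + (1 - beta1) * g
    sl$u <- pmax(beta2 * sl$u, abs(g))
    theta <- theta - corr * sl$m / (sl$u + eps)
    list(theta = theta, sl = sl)
  }
  for (nm in names(grads)) {
    if (startsWith(nm, "bn")) {
      for (sub in c("gamma", "beta")) {
        r <- upd(params[[nm]][[sub]], grads[[nm]][[sub]], state[[nm]][[sub]])
        params[[nm]][[sub]] <- r$theta
        state[[nm]][[sub]] <- r$sl
      }
    } else {
      r <- upd(params[[nm]], grads[[nm]], state[[nm]])
      params[[nm]] <- r$theta
      state[[nm]] <- r$sl
    }
  }
  list(params = params, state = state)
}

#' Train the cluster-aware VAE
#'
#' Optimizes the mean of [vae_loss_terms()] (reconstruction NLL + KL +
#' beta-weighted cluster cross-entropy) with Adamax. The learning rate
#' decays multiplicatively (`decay_rate` per epoch) after epoch 3. A seeded
#' validation split monitors the full loss in inference mode (batch-norm
#' running statistics, no dropout, posterior mean); training stops when it
#' has not improved for `patience` epochs and the best weights are
#' restored.
#'
#' @param model a [build_vae()] model.
#' @param m numeric matrix of (log-standardized) expression values.
#' @param clusters a `cluster_labels` object or integer vector of labels
#'   0..K-1 aligned with rows of `m`.
#' @param verbose print per-epoch losses.
#' @return the trained `vae_model`, with `$history` (tibble of epoch, lr,
#'   train_loss, val_loss).
#' @export
train_vae <- function(model, m, clusters, verbose = FALSE) {
  x <- as.matrix(m)
  cfg <- model$cfg
  labs <- if (inherits(clusters, "cluster_labels")) clusters$assignments else clusters
  stopifnot(length(labs) == nrow(x))
  if (model$use_classifier) {
    stopifnot(max(labs) < model$n_clusters)
    c_onehot <- matrix(0, nrow(x), model$n_clusters)
    c_onehot[cbind(seq_len(nrow(x)), labs + 1L)] <- 1
  } else {
    c_onehot <- NULL
  }

  set.seed(derive_seed(cfg$rng_seed, 12L))
  n <- nrow(x)
  n_val <- max(1L, round(cfg$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  x_tr <- x[tr_idx, , drop = FALSE]
  x_val <- x[val_idx, , drop = FALSE]
  c_tr <- if (!is.null(c_onehot)) c_onehot[tr_idx, , drop = FALSE]
  c_val <- if (!is.null(c_onehot)) c_onehot[val_idx, , drop = FALSE]

  state <- adamax_new(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  hist <- list()

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- cfg$learning_rate * cfg$decay_rate^max(0L, epoch - 3L)
    ord <- sample.int(nrow(x_tr))
    starts <- seq(1L, nrow(x_tr), by = cfg$batch_size)
    tr_losses <- numeric(0)
    for (s in starts) {
      rows <- ord[s:min(s + cfg$batch_size - 1L, nrow(x_tr))]
      if (length(rows) < 2L) next  # batch statistics need >= 2 rows
      xb <- x_tr[rows, , drop = FALSE]
      cb <- if (!is.null(c_tr)) c_tr[rows, , drop = FALSE]
      fw <- vae_forward(model, xb, cb, training = TRUE)
      model$params$bn1 <- fw$f1$bn
      model$params$bn2 <- fw$f3$bn
      if (model$use_classifier) model$params$bn3 <- fw$fc$bn
      lb <- vae_batch_loss(model, xb, cb, fw)
      if (!is.finite(lb)) {
        dv_stop(sprintf("non-finite training loss at epoch %d", epoch),
                "dv_training_error")
      }
      tr_losses <- c(tr_losses, lb)
      grads <- vae_backward(model, xb, cb, fw)
      st <- adamax_step(model$params, grads, state, lr)
      # keep batch-norm running stats updated above; only trainables move
      for (nm in names(grads)) {
        if (startsWith(nm, "bn")) {
          model$params[[nm]]$gamma <- st$params[[nm]]$gamma
          model$params[[nm]]$beta <- st$params[[nm]]$beta
        } else {
          model$params[[nm]] <- st$params[[nm]]
        }
      }
      state <- st$state
    }
    fw_val <- vae_forward(model, x_val, c_val, training = FALSE)
    val_loss <- vae_batch_loss(model, x_val, c_val, fw_val)
    if (!is.finite(val_loss)) {
      dv_stop(sprintf("non-finite validation loss at epoch %d", epoch),
              "dv_training_error")
    }
    hist[[epoch]] <- c(epoch = epoch, lr = lr,
                       train_loss = mean(tr_losses), val_loss = val_loss)
    if (verbose) {
      dv_msg(sprintf("epoch %3d  lr %.2e  train %.3f  val %.3f",
                     epoch, lr, mean(tr_losses), val_loss))
    }
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg$patience) break
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$history <- tibble::as_tibble(do.call(rbind, hist))
  model$best_epoch <- best$epoch
  model
}

#' Embed data with a trained VAE
#'
#' Returns the encoder posterior mean for every row (inference mode:
#' dropout disabled, batch-norm running statistics), so repeated calls are
#' identical.
#'
#' @param model a trained `vae_model`.
#' @param m matrix with the same feature dimension the model was trained on.
#' @return matrix (rows x latent_dim) of latent coordinates.
#' @export
embed_vae <- function(model, m) {
  x <- as.matrix(m)
  if (ncol(x) != model$n_features) {
    dv_stop(sprintf("feature dimension %d does not match model (%d)",
                    ncol(x), model$n_features), "dv_validation_error")
  }
  fw <- vae_forward(model, x, NULL, training = FALSE)
  z <- fw$mu_e
  rownames(z) <- rownames(x)
  colnames(z) <- paste0("latent", seq_len(ncol(z)))
  z
}
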