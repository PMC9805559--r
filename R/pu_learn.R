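# Positive-Unlabeled bagging. Positives are the simulated doublets, the
# unlabeled set is the input cells. Each repetition splits the unlabeled
# set into K folds; a fresh classifier is trained to separate positives
# from one fold and scores the held-out remainder; scores are averaged over
# all (repetition, fold) pairs in which a cell was held out.

#' Logistic-regression classifier (batch-norm + sigmoid) for PU bagging
#'
#' A logistic regression implemented as a minimal network: input ->
#' batch normalization -> dense(1, sigmoid). Trained full-batch with Adamax
#' on binary cross-entropy. The zero-initialized output layer predicts 0.5
#' everywhere before training.
#'
#' @param n_features input dimension (latent dim + 1 for the preliminary
#'   score feature).
#' @return a `pu_classifier` object with elements `fit(x, y, epochs)` and
#'   `predict_proba(x)` semantics via [pu_fit()] / [pu_predict()].
#' @export
make_classifier <- function(n_features) {
  structure(list(
    n_features = as.integer(n_features),
    bn = bn_new(n_features),
    w = rep(0, n_features),
    b = 0,
    loss_curve = numeric(0)
  ), class = "pu_classifier")
}

#' Fit a PU classifier for a fixed number of epochs
#'
#' Full-batch gradient steps (Adamax, learning rate 0.01) on binary
#' cross-entropy; records the loss curve.
#'
#' @param clf a [make_classifier()] object.
#' @param x feature matrix.
#' @param y binary labels (1 = positive/simulated doublet).
#' @param epochs number of full-batch epochs.
#' @param learning_rate Adamax step size.
#' @return the fitted classifier (with `$loss_curve`).
#' @export
pu_fit <- function(clf, x, y, epochs, learning_rate = 0.01) {
  UseMethod("pu_fit")
}

#' @export
pu_fit.pu_classifier <- function(clf, x, y, epochs, learning_rate = 0.01) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(length(y) == n, epochs >= 1L)
  # batch-norm as a fixed standardization from the training batch
  mu <- colMeans(x)
  v <- colMeans(sweep(x, 2L, mu, "-")^2)
  clf$bn$rmean <- mu
  clf$bn$rvar <- v
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, 1 / sqrt(v + BN_EPS), "*")
  w <- clf$w
  b <- clf$b
  mw <- uw <- w * 0
  mb <- ub <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-7
  losses <- numeric(epochs)
  for (t in seq_len(epochs)) {
    eta <- drop(xs %*% w) + b
    p <- stats::plogis(eta)
    losses[t] <- -mean(y * log(pmax(p, 1e-12)) +
                         (1 - y) * log(pmax(1 - p, 1e-12)))
    g <- (p - y) / n
    gw <- drop(crossprod(xs, g))
    gb <- sum(g)
    corr <- learning_rate / (1 - beta1^t)
    mw <- beta1 * mw + (1 - beta1) * gw
    uw <- pmax(beta2 * uw, abs(gw))
    w <- w - corr * mw / (uw + eps)
    mb <- beta1 * mb + (1 - beta1) * gb
    ub <- max(beta2 * ub, abs(gb))
    b <- b - corr * mb / (ub + eps)
  }
  clf$w <- w
  clf$b <- b
  clf$loss_curve <- losses
  clf
}

#' Predict doublet probabilities from a fitted PU classifier
#'
#' @param clf a fitted [make_classifier()] object.
#' @param x feature matrix.
#' @return numeric vector of probabilities in (0, 1).
#' @export
pu_predict <- function(clf, x) {
  UseMethod("pu_predict")
}

#' @export
pu_predict.pu_classifier <- function(clf, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2L, clf$bn$rmean, "-"),
              2L, 1 / sqrt(clf$bn$rvar + BN_EPS), "*")
  stats::plogis(drop(xs %*% clf$w) + clf$b)
}

#' Find the knee of a decreasing loss curve
#'
#' Kneedle-style criterion: both axes are normalized to [0, 1], the
#' decreasing curve is flipped to an increasing difference curve
#' `d(t) = y_norm_flipped(t) - x_norm(t)`, and the knee is the index
#' maximizing `d`. When the curve carries no curvature signal (constant or
#' linear within tolerance) the full probe length is returned.
#'
#' @param loss_curve numeric vector (a decreasing training-loss curve).
#' @param min_gap minimum normalized difference required to accept a knee.
#' @return integer epoch index (1-based) of the knee, or `length(loss_curve)`
#'   when no knee is found.
#' @export
determine_epochs <- function(loss_curve, min_gap = 0.05) {
  n <- length(loss_curve)
  if (n < 3L) return(n)
  rng <- max(loss_curve) - min(loss_curve)
  if (rng <= 0) return(n)
  xn <- (seq_len(n) - 1) / (n - 1)
  yn <- (loss_curve - min(loss_curve)) / rng
  diff_curve <- (1 - yn) - xn      # flipped decreasing curve minus diagonal
  if (max(diff_curve) < min_gap) return(n)
  which.max(diff_curve)
}

#' PU-bagging configuration
#'
#' @param n_reps number of bagging repetitions N (default 5).
#' @param n_folds number of folds K per repetition (default 5).
#' @param epoch_probe length of the probe fit used for knee detection
#'   (default 250 epochs).
#' @param rng_seed integer seed.
#' @return a `pu_config` list.
#' @export
pu_config <- function(n_reps = 5L, n_folds = 5L, epoch_probe = 250L,
                      rng_seed = 1L) {
  stopifnot(n_reps >= 1L, n_folds >= 2L, epoch_probe >= 1L)
  structure(list(n_reps = as.integer(n_reps), n_folds = as.integer(n_folds),
                 epoch_probe = as.integer(epoch_probe),
                 rng_seed = as.integer(rng_seed)),
            class = "pu_config")
}

#' Doublet scores by Positive-Unlabeled bagging
#'
#' For each of N repetitions the unlabeled rows are split into K folds; for
#' each fold a fresh classifier is trained to discriminate the positives
#' from that fold and its predictions are accumulated over the remaining
#' unlabeled rows. The returned score of an unlabeled row is the average of
#' the predictions of every classifier that held it out (N * (K - 1) of
#' them). Positive rows are additionally scored by the average over all
#' N * K classifiers, which the doublet caller uses for its false-negative
#' rate.
#'
#' The training epoch count is chosen once by probing the first fold of the
#' first repetition for `epoch_probe` epochs and locating the knee of the
#' loss curve ([determine_epochs()]); the probe classifier is discarded.
#'
#' @param features matrix (n_unlabeled + n_positive rows) of PU features
#'   (latent embedding with the preliminary score as last column).
#' @param labels binary vector (0 = unlabeled/input cell, 1 = positive/
#'   simulated doublet).
#' @param cfg a [pu_config()].
#' @param classifier_fn factory used to create classifiers; swap for a stub
#'   in tests. Signature `function(n_features)`; the object must work with
#'   [pu_fit()] and [pu_predict()].
#' @return list with `xi` (scores of unlabeled rows, in input order),
#'   `xi_pos` (average scores of positive rows), `epochs` (knee-selected
#'   epoch count) and `counts` (per-unlabeled-row prediction counts).
#' @export
pu_bagging <- function(features, labels, cfg = pu_config(),
                       classifier_fn = make_classifier) {
  x <- as.matrix(features)
  stopifnot(length(labels) == nrow(x))
  u_idx <- which(labels == 0L)
  p_idx <- which(labels == 1L)
  n_u <- length(u_idx)
  if (cfg$n_folds > n_u) {
    dv_stop(sprintf("number of folds (%d) exceeds unlabeled set size (%d)",
                    cfg$n_folds, n_u), "dv_validation_error")
  }
  xp <- x[p_idx, , drop = FALSE]
  xu <- x[u_idx, , drop = FALSE]

  fold_split <- function(rep_i) {
    set.seed(derive_seed(cfg$rng_seed, 100L + rep_i))
    sample(rep_len(seq_len(cfg$n_folds), n_u))
  }

  # probe: first fold of first repetition, long fit, knee of the loss curve
  f1 <- fold_split(1L)
  probe_rows <- rbind(xp, xu[f1 == 1L, , drop = FALSE])
  probe_y <- c(rep(1, nrow(xp)), rep(0, sum(f1 == 1L)))
  probe <- pu_fit(classifier_fn(ncol(x)), probe_rows, probe_y,
                  epochs = cfg$epoch_probe)
  n_epochs <- determine_epochs(probe$loss_curve)

  f_acc <- rep(0, n_u)
  n_acc <- rep(0L, n_u)
  p_acc <- rep(0, length(p_idx))
  n_models <- 0L
  for (rep_i in seq_len(cfg$n_reps)) {
    folds <- fold_split(rep_i)
    for (k in seq_len(cfg$n_folds)) {
      in_fold <- folds == k
      xk <- rbind(xp, xu[in_fold, , drop = FALSE])
      yk <- c(rep(1, nrow(xp)), rep(0, sum(in_fold)))
      clf <- pu_fit(classifier_fn(ncol(x)), xk, yk, epochs = n_epochs)
      held <- which(!in_fold)
      f_acc[held] <- f_acc[held] + pu_predict(clf, xu[held, , drop = FALSE])
      n_acc[held] <- n_acc[held] + 1L
      p_acc <- p_acc + pu_predict(clf, xp)
      n_models <- n_models + 1L
    }
  }
  list(
    xi = f_acc / n_acc,
    xi_pos = p_acc / n_models,
    epochs = n_epochs,
    counts = n_acc
  )
}
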