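test_that("untrained classifier predicts 0.5; predictions stay in (0,1)", {
  clf <- make_classifier(3L)
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(pu_predict(clf, x), rep(0.5, 10))
  fit <- pu_fit(clf, x, rbinom(10, 1, 0.5), epochs = 50L)
  p <- pu_predict(fit, x)
  expect_true(all(p > 0 & p < 1))
})

test_that("the classifier separates linearly separable 1-D data", {
  x <- matrix(c(seq(-2, -1, length.out = 20), seq(1, 2, length.out = 20)), ncol = 1)
  y <- rep(c(0, 1), each = 20)
  fit <- pu_fit(make_classifier(1L), x, y, epochs = 400L)
  acc <- mean((pu_predict(fit, x) > 0.5) == y)
  expect_equal(acc, 1.0)
  expect_lt(fit$loss_curve[400], fit$loss_curve[1])
})

test_that("knee detection finds the analytic knee of an exponential curve", {
  t <- 0:249
  curve <- exp(-t / 5)
  # independent closed form: the Kneedle difference (1 - y_norm) - x_norm is
  # maximal where d/dt [(1 - exp(-t/5)) / (1 - exp(-249/5))] = 1/249,
  # i.e. t = 5 * log(249 / (5 * (1 - exp(-249/5)))) ~ 19.5
  t_analytic <- 5 * log(249 / (5 * (1 - exp(-249 / 5))))
  knee <- determine_epochs(curve)
  expect_lte(abs((knee - 1) - t_analytic), 1)

  # no curvature: linear and constant curves fall back to the probe length
  expect_equal(determine_epochs(seq(1, 0, length.out = 250)), 250L)
  expect_equal(determine_epochs(rep(2, 250)), 250L)
})

test_that("PU bagging with a stub classifier equals the brute-force double loop", {
  set.seed(42)
  n_u <- 11L
  n_p <- 4L
  x <- matrix(rnorm((n_u + n_p) * 3), n_u + n_p, 3)
  labels <- c(rep(0L, n_u), rep(1L, n_p))
  g <- plogis(rowMeans(x))  # the stub's fixed prediction

  for (NK in list(c(1L, 2L), c(3L, 2L), c(2L, 4L))) {
    cfg <- pu_config(n_reps = NK[1], n_folds = NK[2], epoch_probe = 10L,
                     rng_seed = 7L)
    res <- pu_bagging(x, labels, cfg, classifier_fn = new_stub_classifier)
    # identical predictions from every classifier: the average is g itself
    expect_equal(res$xi, g[labels == 0L], tolerance = 1e-12)
    expect_equal(res$xi_pos, g[labels == 1L], tolerance = 1e-12)
    # fold bookkeeping: every unlabeled row held out N*(K-1) times
    expect_true(all(res$counts == NK[1] * (NK[2] - 1L)))
  }
})

test_that("PU bagging reproduces a directly coded fold loop exactly (|U| <= 12, K = 2, N = 1)", {
  set.seed(9)
  n_u <- 12L
  n_p <- 5L
  x <- matrix(rnorm((n_u + n_p) * 2), n_u + n_p, 2)
  labels <- c(rep(0L, n_u), rep(1L, n_p))
  cfg <- pu_config(n_reps = 1L, n_folds = 2L, epoch_probe = 10L, rng_seed = 3L)
  res <- pu_bagging(x, labels, cfg, classifier_fn = new_stub_classifier)

  # brute force: recreate the same fold split, score held-out rows per fold
  set.seed(doubletvae:::derive_seed(3L, 101L))
  folds <- sample(rep_len(1:2, n_u))
  f_acc <- rep(0, n_u)
  n_acc <- rep(0L, n_u)
  for (k in 1:2) {
    held <- which(folds != k)
    pred <- plogis(rowMeans(x[labels == 0L, , drop = FALSE][held, , drop = FALSE]))
    f_acc[held] <- f_acc[held] + pred
    n_acc[held] <- n_acc[held] + 1L
  }
  expect_identical(res$xi, f_acc / n_acc)
})

test_that("scores lie in [0,1], and more repetitions stabilize them", {
  set.seed(30)
  n_u <- 60L
  n_p <- 20L
  x <- rbind(matrix(rnorm(n_u * 3), n_u, 3),
             matrix(rnorm(n_p * 3, mean = 1.5), n_p, 3))
  labels <- c(rep(0L, n_u), rep(1L, n_p))
  xi <- lapply(c(1L, 4L), function(N) {
    pu_bagging(x, labels, pu_config(n_reps = N, n_folds = 4L,
                                    epoch_probe = 50L, rng_seed = 11L))$xi
  })
  xi_ref <- pu_bagging(x, labels, pu_config(n_reps = 8L, n_folds = 4L,
                                            epoch_probe = 50L,
                                            rng_seed = 99L))$xi
  expect_true(all(unlist(xi) >= 0 & unlist(xi) <= 1))
  # deviation from a deeply averaged reference shrinks as N grows
  expect_lt(mean(abs(xi[[2]] - xi_ref)), mean(abs(xi[[1]] - xi_ref)))
})

test_that("more folds than unlabeled rows is an error", {
  x <- matrix(rnorm(12), 6, 2)
  labels <- c(0L, 0L, 0L, 1L, 1L, 1L)
  expect_error(pu_bagging(x, labels, pu_config(n_folds = 4L)),
               class = "dv_validation_error")
})
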