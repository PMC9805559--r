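# helper: deterministic forward pass for gradient checking - fixes dropout
# masks and latent noise by resetting the RNG before each forward call
fixed_forward <- function(model, x, c_onehot, seed = 123L) {
  set.seed(seed)
  doubletvae:::vae_forward(model, x, c_onehot, training = TRUE)
}

test_that("model heads have the contracted shapes and positivity", {
  cfg <- vae_config(latent_dim = 5L, hidden_units = 16L, rng_seed = 1L)
  model <- build_vae(100L, 3L, cfg)
  set.seed(2)
  x <- matrix(rnorm(8 * 100), 8, 100)
  fw <- fixed_forward(model, x, matrix(1 / 3, 8, 3))
  expect_equal(dim(fw$mu_e), c(8L, 5L))
  expect_equal(dim(fw$mu_d), c(8L, 100L))
  expect_true(all(fw$sig_e > 0))
  expect_true(all(fw$sig_d > 0))
  expect_equal(rowSums(fw$zeta), rep(1, 8), tolerance = 1e-6)
})

test_that("loss terms match the closed forms", {
  x <- matrix(0, 2, 3)
  mu_d <- x
  sig_d <- matrix(1, 2, 3)
  # KL is 0 at (mu = 0, sigma = 1)
  terms <- vae_loss_terms(x, mu_d, sig_d,
                          mu_e = matrix(0, 2, 5), sigma_e = matrix(1, 2, 5))
  expect_equal(terms$kl, c(0, 0))
  # and 0.5 at mu = e1, sigma = 1
  mu_e <- matrix(0, 2, 5)
  mu_e[, 1] <- 1
  terms2 <- vae_loss_terms(x, mu_d, sig_d, mu_e, matrix(1, 2, 5))
  expect_equal(terms2$kl, c(0.5, 0.5))
  # reconstruction NLL of x = mu under unit sigma is the Gaussian constant
  expect_equal(terms$nll, rep(3 * 0.5 * log(2 * pi), 2))
  # perfect one-hot classification has zero cross-entropy
  c1 <- matrix(c(1, 0, 0, 1), 2, 2)
  terms3 <- vae_loss_terms(x, mu_d, sig_d, mu_e, matrix(1, 2, 5),
                           c_onehot = c1, zeta = c1)
  expect_equal(terms3$cce, c(0, 0))
})

test_that("KL term is non-negative and zero only at the prior", {
  set.seed(4)
  for (i in 1:20) {
    mu <- matrix(rnorm(5), 1, 5)
    sig <- matrix(exp(rnorm(5) / 2), 1, 5)
    kl <- vae_loss_terms(matrix(0, 1, 1), matrix(0, 1, 1), matrix(1, 1, 1),
                         mu, sig)$kl
    expect_gte(kl, 0)
  }
})

test_that("analytic gradients agree with numerical differentiation", {
  cfg <- vae_config(latent_dim = 2L, hidden_units = 4L, rng_seed = 6L,
                    beta = 50, dropout_rate = 0.3)
  model <- build_vae(3L, 2L, cfg)
  set.seed(5)
  x <- matrix(rnorm(6 * 3), 6, 3)
  conehot <- matrix(0, 6, 2)
  conehot[cbind(1:6, rep(1:2, 3))] <- 1

  loss_at <- function(params) {
    m2 <- model
    m2$params <- params
    fw <- fixed_forward(m2, x, conehot)
    doubletvae:::vae_batch_loss(m2, x, conehot, fw)
  }
  fw <- fixed_forward(model, x, conehot)
  grads <- doubletvae:::vae_backward(model, x, conehot, fw)

  h <- 1e-5
  check <- function(path) {
    g_ana <- if (length(path) == 2L) grads[[path[1]]][[path[2]]] else grads[[path]]
    theta <- if (length(path) == 2L) model$params[[path[1]]][[path[2]]] else model$params[[path]]
    idx <- seq_len(min(6L, length(theta)))
    for (i in idx) {
      pp <- model$params
      bump <- function(delta) {
        if (length(path) == 2L) pp[[path[1]]][[path[2]]][i] <- theta[i] + delta
        else pp[[path]][i] <- theta[i] + delta
        pp
      }
      g_num <- (loss_at(bump(h)) - loss_at(bump(-h))) / (2 * h)
      expect_equal(unname(as.vector(g_ana)[i]), g_num, tolerance = 1e-4)
    }
  }
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4", "W5", "b5")) check(nm)
  for (bn in c("bn1", "bn2", "bn3")) for (sub in c("gamma", "beta")) check(c(bn, sub))
})

test_that("training reduces the loss on a structured fixture and is seed-deterministic", {
  bl <- make_blobs(n_per = 100L, dim = 30L, sep = 10, seed = 9L)
  cfg <- vae_config(hidden_units = 32L, max_epochs = 15L, patience = 20L,
                    rng_seed = 31L, batch_size = 32L)
  model <- build_vae(30L, 2L, cfg)
  fit <- train_vae(model, bl$x, bl$blob)
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])

  fit2 <- train_vae(build_vae(30L, 2L, cfg), bl$x, bl$blob)
  expect_identical(fit$history, fit2$history)
})

test_that("early stopping halts after patience epochs without improvement", {
  bl <- make_blobs(n_per = 40L, dim = 10L, sep = 0.1, seed = 13L)
  cfg <- vae_config(hidden_units = 8L, max_epochs = 200L, patience = 0L,
                    rng_seed = 3L, batch_size = 16L)
  fit <- train_vae(build_vae(10L, 2L, cfg), bl$x, bl$blob)
  # with patience 0 training must stop at the first epoch whose validation
  # loss fails to improve
  vl <- fit$history$val_loss
  n <- length(vl)
  expect_true(n == 200L || vl[n] >= min(vl[seq_len(n - 1L)]))
  if (n < 200L) expect_equal(which.min(vl), n - 1L)
})

test_that("embedding is deterministic, permutation-equivariant and shaped", {
  bl <- make_blobs(n_per = 50L, dim = 20L, sep = 12, seed = 21L)
  cfg <- vae_config(hidden_units = 16L, max_epochs = 10L, rng_seed = 8L,
                    batch_size = 32L)
  fit <- train_vae(build_vae(20L, 2L, cfg), bl$x, bl$blob)
  z1 <- embed_vae(fit, bl$x)
  z2 <- embed_vae(fit, bl$x)
  expect_identical(z1, z2)
  expect_equal(dim(z1), c(100L, 5L))
  perm <- sample(100L)
  expect_equal(embed_vae(fit, bl$x[perm, ]), z1[perm, ], ignore_attr = TRUE)
  expect_error(embed_vae(fit, bl$x[, 1:5]), class = "dv_validation_error")
})

test_that("latent space keeps blob labels knn-classifiable", {
  bl <- make_blobs(n_per = 100L, dim = 40L, sep = 15, seed = 17L)
  cl <- cluster_cells(bl$x, n_pcs = 10L, rng_seed = 2L)
  cfg <- vae_config(hidden_units = 64L, max_epochs = 30L, rng_seed = 12L)
  fit <- train_vae(build_vae(40L, cl$n_clusters, cfg), bl$x, cl)
  z <- embed_vae(fit, bl$x)
  nn <- doubletvae:::knn_index(z, 5L)
  votes <- rowMeans(matrix(bl$blob[nn] == 1L, nrow(nn), ncol(nn)))
  acc <- mean((votes > 0.5) == (bl$blob == 1L))
  expect_gte(acc, 0.95)
})

test_that("with beta = 0 the loss reduces to the plain VAE objective", {
  set.seed(3)
  x <- matrix(rnorm(12), 4, 3)
  mu_d <- x * 0.9
  sig_d <- matrix(1.2, 4, 3)
  mu_e <- matrix(0.3, 4, 2)
  sig_e <- matrix(0.8, 4, 2)
  cfull <- matrix(c(1, 0), 4, 2, byrow = TRUE)
  zeta <- matrix(c(0.6, 0.4), 4, 2, byrow = TRUE)
  t_ab <- vae_loss_terms(x, mu_d, sig_d, mu_e, sig_e, cfull, zeta)
  plain <- mean(t_ab$nll) + mean(t_ab$kl)
  expect_equal(plain + 0 * mean(t_ab$cce), plain)
  expect_gt(mean(t_ab$cce), 0)
})
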