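test_that("simulated doublets sum parent rows and rescale to an eligible library size", {
  # rows (2,0) and (0,2): precursor (2,2); eligible sizes {2,2,4} >= 2
  x <- count_matrix(rbind(c(2, 0), c(0, 2), c(2, 2)))
  sim <- simulate_doublets(x, n_sim = 200L, rng_seed = 1L)
  lib <- rowSums(unclass(x))
  for (d in seq_len(200L)) {
    pa <- sim$parents[d, ]
    expect_true(pa[1] != pa[2])
    row <- unclass(sim$doublets)[d, ]
    pre <- unclass(x)[pa[1], ] + unclass(x)[pa[2], ]
    # scaled precursor: direction preserved
    expect_equal(row / sum(row), pre / sum(pre))
    # library size equals an observed size >= the larger parent size
    expect_true(any(abs(sum(row) - lib) < 1e-9))
    expect_gte(sum(row), max(lib[pa]) - 1e-9)
  }
  # the (2,0)+(0,2) pairing scaled to 4 gives (2,2)
  hit <- which(sim$parents[, 1] != 3 & sim$parents[, 2] != 3 &
                 abs(rowSums(unclass(sim$doublets)) - 4) < 1e-9)
  expect_true(length(hit) > 0)
  expect_equal(unname(unclass(sim$doublets)[hit[1], ]), c(2, 2))
})

test_that("a 2-row matrix always pairs the two rows, and seeding is reproducible", {
  x <- count_matrix(rbind(c(3, 1), c(0, 5)))
  sim <- simulate_doublets(x, n_sim = 50L, rng_seed = 9L)
  expect_true(all(apply(sim$parents, 1, function(p) setequal(p, c(1, 2)))))
  sim2 <- simulate_doublets(x, n_sim = 50L, rng_seed = 9L)
  expect_identical(unclass(sim$doublets), unclass(sim2$doublets))
  expect_identical(sim$parents, sim2$parents)
})

test_that("preliminary knn scores are neighbour fractions with correct boundaries", {
  # 4 points on a line: real at 0, 1; simulated at 10, 11; k = 1
  m <- matrix(c(0, 1, 10, 11), 4, 1)
  s <- preliminary_knn_scores(m, labels = c(0, 0, 1, 1), k = 1L, n_pcs = 0L)
  expect_equal(s, c(0, 0, 1, 1))

  # k = 2: every point's two nearest neighbours are one real, one simulated
  s2 <- preliminary_knn_scores(m, labels = c(0, 0, 1, 1), k = 2L, n_pcs = 0L)
  expect_equal(s2, rep(0.5, 4))
})

test_that("preliminary knn scores are permutation-equivariant", {
  set.seed(31)
  m <- matrix(rnorm(60 * 5), 60, 5)
  labels <- rep(c(0L, 1L), 30)
  s <- preliminary_knn_scores(m, labels, k = 7L, n_pcs = 3L)
  perm <- sample(60)
  s_perm <- preliminary_knn_scores(m[perm, ], labels[perm], k = 7L, n_pcs = 3L)
  expect_equal(s_perm, s[perm], tolerance = 1e-12)
})

test_that("doublet-count estimate follows the linear-interpolation quantile", {
  s <- c(0.1, 0.4, 0.5, 0.2, 0.4, 0.6, 0.8)
  labels <- c(0, 0, 0, 1, 1, 1, 1)
  # 25% quantile of (0.2, 0.4, 0.6, 0.8) by linear interpolation = 0.35
  expect_equal(estimate_num_doublets(s, labels, 0.25), 2L)

  # separated case: simulated all above real
  expect_equal(estimate_num_doublets(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0L)

  # all identical scores: every real cell counted
  expect_equal(estimate_num_doublets(rep(0.3, 6), c(0, 0, 0, 1, 1, 1)), 3L)
})

test_that("doublet-count estimate is monotone non-increasing in the quantile", {
  set.seed(12)
  s <- runif(200)
  labels <- rep(c(0L, 1L), each = 100L)
  qs <- seq(0.05, 0.95, by = 0.05)
  counts <- vapply(qs, function(q) estimate_num_doublets(s, labels, q), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("subsampling is score-proportional without replacement", {
  expect_identical(subsample_doublets(c(1, 2, 3), 3L), 1:3)
  expect_identical(subsample_doublets(c(1, 0, 0), 1L, rng_seed = 4L), 1L)

  # scores (3, 1): P(first drawn) = 0.75; Monte Carlo over 10,000 seeds
  draws <- vapply(seq_len(10000L), function(i) {
    subsample_doublets(c(3, 1), 1L, rng_seed = i)
  }, integer(1))
  expect_equal(mean(draws == 1L), 0.75, tolerance = 0.02)

  # shortfall filled uniformly from zero-score rows
  keep <- subsample_doublets(c(2, 0, 0, 0), 2L, rng_seed = 2L)
  expect_true(1L %in% keep)
  expect_length(keep, 2L)

  # reproducible under a fixed seed
  set.seed(77)
  sc <- runif(50)
  expect_identical(subsample_doublets(sc, 20L, rng_seed = 8L),
                   subsample_doublets(sc, 20L, rng_seed = 8L))
})
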