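test_that("well-separated blobs are never mixed within a cluster", {
  bl <- make_blobs(n_per = 100L, sep = 20)
  cl <- cluster_cells(bl$x, n_pcs = 5L, rng_seed = 1L)
  # at least the two blobs are told apart...
  expect_gte(cl$n_clusters, 2L)
  # ...and the partition refines blob membership: every cluster is pure
  # (modularity at resolution 1 may split a diffuse blob into sub-
  # communities, which is harmless downstream, but must never merge blobs)
  tab <- table(cl$assignments, bl$blob)
  expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1L))
})

test_that("the meta-cell path activates above the threshold and matches the direct path", {
  bl <- make_blobs(n_per = 120L, sep = 20, seed = 3L)
  direct <- cluster_cells(bl$x, small_threshold = 1000L, n_pcs = 5L,
                          rng_seed = 1L)
  meta <- cluster_cells(bl$x, small_threshold = 100L, n_pcs = 5L,
                        meta_fraction = 0.2, rng_seed = 1L)
  # both paths agree on blob membership (labels may swap)
  agree <- function(cl) {
    tab <- table(cl$assignments, bl$blob)
    all(apply(tab, 1, function(r) sum(r > 0)) == 1L)
  }
  expect_true(agree(direct))
  expect_true(agree(meta))
})

test_that("clustering is deterministic given the seed and constant on duplicated rows", {
  bl <- make_blobs(n_per = 60L, sep = 15, seed = 5L)
  x <- rbind(bl$x, bl$x[1, , drop = FALSE])  # duplicate of row 1
  c1 <- cluster_cells(x, n_pcs = 5L, rng_seed = 2L)
  c2 <- cluster_cells(x, n_pcs = 5L, rng_seed = 2L)
  expect_identical(c1$assignments, c2$assignments)
  expect_equal(c1$assignments[nrow(x)], c1$assignments[1])
  # labels contiguous from 0
  expect_setequal(unique(c1$assignments), seq_len(c1$n_clusters) - 1L)
})

test_that("homotypic exclusion drops exactly the same-cluster parent pairs", {
  clusters <- structure(list(assignments = c(2L, 2L, 0L, 3L, 1L, 1L),
                             n_clusters = 4L), class = "cluster_labels")
  parents <- rbind(c(1L, 2L),  # c=2,2 -> dropped
                   c(1L, 4L),  # 2,3  -> kept
                   c(3L, 4L),  # 0,3  -> kept
                   c(5L, 6L))  # 1,1  -> dropped
  keep <- exclude_homotypic(parents, clusters)
  expect_identical(keep, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("a single real cluster marks every simulated doublet homotypic", {
  # one blob only: all parents share the single cluster
  set.seed(8)
  x <- count_matrix(matrix(rpois(150 * 40, 8), 150, 40))
  sim <- simulate_doublets(x, n_sim = 60L, rng_seed = 2L)
  clusters <- structure(list(assignments = rep(0L, 210L), n_clusters = 1L),
                        class = "cluster_labels")
  keep <- exclude_homotypic(sim$parents, clusters)
  expect_true(all(!keep))
  # and the pipeline reports the collapse as a descriptive error
  expect_error(
    suppressWarnings(
      run_pipeline(x, pipeline_config(rng_seed = 1L, verbose = FALSE,
                                      resolution = 0.0001,
                                      vae = vae_config(max_epochs = 3L)))),
    class = "dv_homotypic_collapse")
})
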