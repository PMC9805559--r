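# Shared fixtures, built in code.

# two well-separated Gaussian blobs (rows = points)
make_blobs <- function(n_per = 100L, dim = 10L, sep = 20, seed = 42L) {
  set.seed(seed)
  a <- matrix(rnorm(n_per * dim), n_per, dim)
  b <- matrix(rnorm(n_per * dim), n_per, dim)
  b[, 1L] <- b[, 1L] + sep
  list(x = rbind(a, b), blob = rep(c(0L, 1L), each = n_per))
}

# a small deterministic count matrix
small_counts <- function(n = 6L, p = 4L, seed = 11L) {
  set.seed(seed)
  count_matrix(matrix(rpois(n * p, 5), n, p))
}

# cache expensive end-to-end runs across test files (computed at most once
# per test session)
.dv_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .dv_cache)) {
    assign(key, force(expr), envir = .dv_cache)
  }
  get(key, envir = .dv_cache)
}

# the default synthetic study fixture and one full pipeline run on it
default_fixture <- function() {
  cached("default_fixture", generate_dataset(synthetic_spec()))
}

default_run <- function() {
  cached("default_run", {
    ds <- default_fixture()
    run_pipeline(ds$counts, pipeline_config(rng_seed = 20240901L,
                                            verbose = FALSE))
  })
}

# a small pipeline run used where full scale is not needed
small_run <- function(seed = 5L) {
  cached(paste0("small_run_", seed), {
    ds <- small_fixture()
    run_pipeline(ds$counts,
                 pipeline_config(rng_seed = seed, verbose = FALSE,
                                 vae = vae_config(max_epochs = 40L)))
  })
}

small_fixture <- function() {
  cached("small_fixture",
         generate_dataset(synthetic_spec(n_singlets = 400L, n_genes = 500L,
                                         rng_seed = 7L)))
}
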