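#' Specification for a synthetic scRNA-seq dataset with known doublets
#'
#' Describes a multi-cell-type negative-binomial count matrix with a known
#' fraction of injected doublets, used to exercise every pipeline stage
#' without external data. Each cell type shares a lognormal baseline
#' expression profile with a type-specific block of marker genes scaled up
#' by `type_mean_scale`; per-cell counts are negative binomial around the
#' type profile with lognormal library sizes. Doublets are sums of two
#' freshly drawn singlet count vectors — from different types (heterotypic)
#' or, for a configurable fraction, from the same type (homotypic, the hard
#' case).
#'
#' @param n_singlets number of singlet cells (default 2000).
#' @param n_genes number of genes (default 1500).
#' @param n_types number of cell types (default 5, >= 2).
#' @param doublet_rate fraction of all output rows that are doublets, in
#'   [0, 1) (default 0.10).
#' @param homotypic_fraction fraction of injected doublets whose two parents
#'   share a type (default 0.2).
#' @param type_mean_scale fold-change of marker genes over baseline
#'   (default 10).
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   mu + phi * mu^2; default 0.1).
#' @param libsize_meanlog,libsize_sdlog lognormal library-size parameters
#'   (defaults log(2500) and 0.3, typical droplet UMI depths).
#' @param rng_seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_singlets = 2000L, n_genes = 1500L, n_types = 5L,
                           doublet_rate = 0.10, homotypic_fraction = 0.2,
                           type_mean_scale = 10, nb_dispersion = 0.1,
                           libsize_meanlog = log(2500), libsize_sdlog = 0.3,
                           rng_seed = 1L) {
  stopifnot(n_types >= 2L, doublet_rate >= 0, doublet_rate < 1,
            homotypic_fraction >= 0, homotypic_fraction <= 1,
            type_mean_scale > 0, nb_dispersion > 0)
  structure(list(n_singlets = as.integer(n_singlets),
                 n_genes = as.integer(n_genes), n_types = as.integer(n_types),
                 doublet_rate = doublet_rate,
                 homotypic_fraction = homotypic_fraction,
                 type_mean_scale = type_mean_scale,
                 nb_dispersion = nb_dispersion,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

# one NB singlet count vector for a given type profile (probabilities pi)
draw_singlet_counts <- function(pi_type, libsize, phi) {
  mu <- libsize * pi_type
  rnbinom(length(mu), size = 1 / phi, mu = mu)
}

#' Generate a synthetic count matrix with ground-truth doublet labels
#'
#' The number of injected doublets is
#' `round(doublet_rate * n_singlets / (1 - doublet_rate))`, so doublets make
#' up `doublet_rate` of all output rows. Rows are shuffled; the returned
#' truth vector is aligned with the shuffled matrix. Generation is
#' bit-reproducible given `rng_seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `counts` (a [count_matrix()]), `truth` (logical, TRUE =
#'   doublet), `type` (parent type of each row; doublets carry
#'   `"typeA+typeB"`), and `homotypic` (logical, TRUE for homotypic
#'   doublets, NA for singlets).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$rng_seed)
  p <- spec$n_genes
  K <- spec$n_types

  baseline <- rlnorm(p, meanlog = 0, sdlog = 1)
  # disjoint marker blocks, one per type, covering up to half the genes
  block <- max(1L, floor(p / (2L * K)))
  profiles <- matrix(rep(baseline, K), nrow = K, byrow = TRUE)
  for (t in seq_len(K)) {
    idx <- ((t - 1L) * block + 1L):(t * block)
    profiles[t, idx] <- profiles[t, idx] * spec$type_mean_scale
  }
  profiles <- profiles / rowSums(profiles)

  n_dbl <- round(spec$doublet_rate * spec$n_singlets / (1 - spec$doublet_rate))
  type_of <- sample.int(K, spec$n_singlets, replace = TRUE)
  lib <- rlnorm(spec$n_singlets, spec$libsize_meanlog, spec$libsize_sdlog)
  singlets <- t(vapply(seq_len(spec$n_singlets), function(i) {
    draw_singlet_counts(profiles[type_of[i], ], lib[i], spec$nb_dispersion)
  }, numeric(p)))

  if (n_dbl > 0L) {
    homo <- runif(n_dbl) < spec$homotypic_fraction
    pair_types <- t(vapply(seq_len(n_dbl), function(i) {
      if (homo[i]) {
        tt <- sample.int(K, 1L)
        c(tt, tt)
      } else {
        sample.int(K, 2L)
      }
    }, integer(2L)))
    lib_d <- rlnorm(2L * n_dbl, spec$libsize_meanlog, spec$libsize_sdlog)
    doublets <- t(vapply(seq_len(n_dbl), function(i) {
      a <- draw_singlet_counts(profiles[pair_types[i, 1L], ],
                               lib_d[2L * i - 1L], spec$nb_dispersion)
      b <- draw_singlet_counts(profiles[pair_types[i, 2L], ],
                               lib_d[2L * i], spec$nb_dispersion)
      a + b
    }, numeric(p)))
    counts <- rbind(singlets, doublets)
    truth <- c(rep(FALSE, spec$n_singlets), rep(TRUE, n_dbl))
    type <- c(paste0("type", type_of),
              paste0("type", pair_types[, 1L], "+type", pair_types[, 2L]))
    homotypic <- c(rep(NA, spec$n_singlets), homo)
  } else {
    counts <- singlets
    truth <- rep(FALSE, spec$n_singlets)
    type <- paste0("type", type_of)
    homotypic <- rep(NA, spec$n_singlets)
  }

  ord <- sample.int(nrow(counts))
  counts <- counts[ord, , drop = FALSE]
  rownames(counts) <- sprintf("BC%05d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("G%04d", seq_len(p))
  list(counts = count_matrix(counts),
       truth = truth[ord],
       type = type[ord],
       homotypic = homotypic[ord])
}

#' Write a synthetic dataset as an MTX directory plus truth CSV
#'
#' @param ds result of [generate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  write_counts_mtx(ds$counts, dir)
  write.csv(data.frame(barcode = rownames(ds$counts), doublet = ds$truth,
                       type = ds$type, homotypic = ds$homotypic),
            file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
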