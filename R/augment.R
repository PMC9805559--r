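#' Simulate artificial doublets from observed cells
#'
#' For each artificial doublet a pair of distinct rows (i, j) is drawn
#' uniformly at random and summed into a precursor. A target library size
#' is then drawn uniformly (with replacement across doublets) from the
#' multiset of observed library sizes that are at least as large as the
#' larger of the two parents' library sizes, and the precursor is rescaled
#' to that total. Parent index pairs are retained so that homotypic
#' simulated doublets can be excluded after clustering.
#'
#' Rescaled doublet rows are kept as reals; downstream transforms do not
#' require integral counts.
#'
#' @param x a [count_matrix()] of real cells (>= 2 rows).
#' @param n_sim number of doublets to simulate (default: one per real cell).
#' @param rng_seed integer seed.
#' @param max_retries resampling attempts when a drawn pair has an all-zero
#'   precursor.
#' @return list with `doublets` (a [count_matrix()] of `n_sim` rows) and
#'   `parents` (integer matrix `n_sim` x 2 of parent row indices).
#' @export
simulate_doublets <- function(x, n_sim = nrow(x), rng_seed = 1L,
                              max_retries = 100L) {
  m <- unclass(x)
  n <- nrow(m)
  stopifnot(n >= 2L, n_sim >= 1L)
  set.seed(rng_seed)
  lib <- rowSums(m)
  lib_sorted <- sort(lib)
  out <- matrix(0, n_sim, ncol(m))
  parents <- matrix(0L, n_sim, 2L)
  for (d in seq_len(n_sim)) {
    for (try in seq_len(max_retries)) {
      ij <- sample.int(n, 2L)                 # without replacement: i != j
      pre <- m[ij[1L], ] + m[ij[2L], ]
      tot <- sum(pre)
      if (tot > 0) break
      if (try == max_retries) {
        dv_stop("could not draw a doublet pair with positive total count",
                "dv_simulation_error")
      }
    }
    lo <- max(lib[ij[1L]], lib[ij[2L]])
    eligible <- lib_sorted[lib_sorted >= lo]
    ell <- if (length(eligible)) eligible[[sample.int(length(eligible), 1L)]] else tot
    out[d, ] <- ell * pre / tot
    parents[d, ] <- ij
  }
  rownames(out) <- paste0("simdbl", seq_len(n_sim))
  colnames(out) <- colnames(m)
  list(
    doublets = count_matrix(out),
    parents = parents
  )
}

#' Stack real cells and simulated doublets into an augmented set
#'
#' @param x real-cell [count_matrix()].
#' @param sim result of [simulate_doublets()].
#' @return list with `matrix` (rows: real then simulated), `labels`
#'   (0 = input cell, 1 = simulated doublet), `parents`, and `n_real`.
#' @export
augment_counts <- function(x, sim) {
  stopifnot(identical(colnames(x), colnames(sim$doublets)))
  aug <- rbind(unclass(x), unclass(sim$doublets))
  list(
    matrix = count_matrix(aug),
    labels = c(rep(0L, nrow(x)), rep(1L, nrow(sim$doublets))),
    parents = sim$parents,
    n_real = nrow(x)
  )
}

#' Preliminary doublet score from the simulated-neighbour fraction
#'
#' Projects the (standardized) augmented matrix onto its leading principal
#' components, finds each row's k nearest neighbours (Euclidean, self
#' excluded) and scores every row by the fraction of those neighbours that
#' are simulated doublets.
#'
#' @param m numeric matrix (augmented, standardized); or a precomputed PC
#'   score matrix when `n_pcs = 0`.
#' @param labels binary vector, 1 marking simulated-doublet rows.
#' @param k neighbourhood size; default `ceiling(sqrt(nrow(m)))`, the usual
#'   square-root heuristic for neighbourhood graphs.
#' @param n_pcs principal components used before the neighbour search
#'   (0 skips projection).
#' @return numeric vector of scores in [0, 1], one per row.
#' @export
preliminary_knn_scores <- function(m, labels, k = NULL, n_pcs = 30L) {
  m <- as.matrix(m)
  stopifnot(length(labels) == nrow(m))
  if (is.null(k)) k <- as.integer(ceiling(sqrt(nrow(m))))
  stopifnot(k >= 1L, k < nrow(m))
  z <- if (n_pcs > 0L) pca_project(m, n_pcs) else m
  nn <- knn_index(z, k)
  sim <- as.numeric(labels == 1L)
  rowMeans(matrix(sim[nn], nrow(nn), ncol(nn)))
}

#' Estimate the number of real doublets in the input
#'
#' The cutoff is the given quantile (linear-interpolation convention,
#' `stats::quantile` type 7) of the simulated doublets' preliminary scores;
#' the estimate is the number of input cells scoring at or above it.
#'
#' @param s preliminary scores over all augmented rows.
#' @param labels binary vector (1 = simulated doublet).
#' @param quantile_cut quantile of simulated scores used as cutoff
#'   (default 0.25).
#' @return integer estimate of the number of doublets among input cells.
#' @export
estimate_num_doublets <- function(s, labels, quantile_cut = 0.25) {
  stopifnot(length(s) == length(labels), any(labels == 1L), any(labels == 0L))
  cut <- unname(quantile(s[labels == 1L], probs = quantile_cut, type = 7))
  sum(s[labels == 0L] >= cut)
}

#' Subsample simulated doublets in proportion to their scores
#'
#' Draws `n_keep` distinct simulated rows without replacement with
#' probability proportional to score. If fewer than `n_keep` rows have a
#' positive score, the shortfall is drawn uniformly from the zero-score
#' rows.
#'
#' @param sim_scores non-negative preliminary scores of the simulated rows.
#' @param n_keep number of rows to retain, `0 <= n_keep <= length(sim_scores)`.
#' @param rng_seed integer seed.
#' @return sorted integer vector of retained simulated-row indices.
#' @export
subsample_doublets <- function(sim_scores, n_keep, rng_seed = 1L) {
  n_sim <- length(sim_scores)
  stopifnot(n_keep >= 0L, n_keep <= n_sim, all(sim_scores >= 0))
  if (n_keep == 0L) return(integer(0))
  if (n_keep == n_sim) return(seq_len(n_sim))
  set.seed(rng_seed)
  pos <- which(sim_scores > 0)
  zero <- which(sim_scores == 0)
  if (length(pos) >= n_keep) {
    keep <- pos[sample.int(length(pos), n_keep, prob = sim_scores[pos])]
  } else {
    extra <- zero[sample.int(length(zero), n_keep - length(pos))]
    keep <- c(pos, extra)
  }
  sort(keep)
}
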