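#' Full pipeline configuration
#'
#' Collects the per-stage options behind one object; every stochastic stage
#' draws its own stream from the single `rng_seed`, so one seed fixes the
#' whole run.
#'
#' @param n_top_genes variable genes kept after sparsity filtering
#'   (default 2000).
#' @param max_zero_fraction sparsity filter threshold (default 0.99).
#' @param n_pcs principal components used for neighbour searches and
#'   clustering (default 30).
#' @param prelim_k neighbourhood size for the preliminary doublet score;
#'   `NULL` (default) uses `ceiling(sqrt(rows))` of the augmented matrix.
#' @param quantile_cut quantile of simulated scores defining the
#'   doublet-count cutoff (default 0.25).
#' @param small_threshold,meta_fraction,knn_k,resolution clustering options,
#'   see [cluster_cells()].
#' @param vae a [vae_config()]; its `rng_seed` is overwritten by the global
#'   seed.
#' @param pu a [pu_config()]; its `rng_seed` is overwritten likewise.
#' @param expected_doublets optional user expectation for the number of
#'   doublets (`mu`); `NULL` uses the `n^2 * 1e-5` heuristic.
#' @param call whether to derive binary calls (default TRUE).
#' @param rng_seed global integer seed.
#' @param verbose stage-progress messages (default TRUE).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_top_genes = 2000L, max_zero_fraction = 0.99,
                            n_pcs = 30L, prelim_k = NULL, quantile_cut = 0.25,
                            small_threshold = 1000L, meta_fraction = 0.10,
                            knn_k = 15L, resolution = 1.0,
                            vae = vae_config(), pu = pu_config(),
                            expected_doublets = NULL, call = TRUE,
                            rng_seed = 1L, verbose = TRUE) {
  structure(list(n_top_genes = n_top_genes,
                 max_zero_fraction = max_zero_fraction,
                 n_pcs = n_pcs, prelim_k = prelim_k,
                 quantile_cut = quantile_cut,
                 small_threshold = small_threshold,
                 meta_fraction = meta_fraction,
                 knn_k = knn_k, resolution = resolution,
                 vae = vae, pu = pu,
                 expected_doublets = expected_doublets,
                 call = call,
                 rng_seed = as.integer(rng_seed), verbose = verbose),
            class = "pipeline_config")
}

#' Annotate doublets in a raw count matrix
#'
#' Runs the full annotation pipeline: doublet simulation and augmentation;
#' gene filtering and variable-gene selection on the augmented matrix;
#' preliminary k-nearest-neighbour doublet scores; estimation of the number
#' of real doublets and score-proportional subsampling of the simulated
#' set; Leiden clustering (directly or through meta-cells) and removal of
#' homotypic simulated doublets; cluster-aware VAE embedding;
#' positive-unlabeled bagging for final scores; and composite-cost
#' thresholding for binary calls.
#'
#' @param x a [count_matrix()] (or a path accepted by [load_counts()]).
#' @param config a [pipeline_config()].
#' @return an object of class `doublet_result`; see [tidy.doublet_result()].
#' @export
run_pipeline <- function(x, config = pipeline_config()) {
  cfg <- config
  t0 <- Sys.time()
  if (is.character(x)) x <- load_counts(x)
  if (!inherits(x, "count_matrix")) x <- count_matrix(x)

  lib <- rowSums(unclass(x))
  if (any(lib == 0)) {
    warning(sprintf("dropping %d barcodes with zero total counts", sum(lib == 0)))
    x <- count_matrix(unclass(x)[lib > 0, , drop = FALSE])
  }
  n <- nrow(x)
  dv_msg(sprintf("input: %d barcodes x %d genes", n, ncol(x)),
         verbose = cfg$verbose)

  ## --- augmentation -------------------------------------------------------
  sim <- simulate_doublets(x, n_sim = n, rng_seed = derive_seed(cfg$rng_seed, 1L))
  aug <- augment_counts(x, sim)
  dv_msg(sprintf("simulated %d artificial doublets", n), verbose = cfg$verbose)

  aug_f <- filter_sparse_genes(aug$matrix, cfg$max_zero_fraction)
  aug_f <- select_variable_genes(aug_f, cfg$n_top_genes)
  dv_msg(sprintf("kept %d genes after sparsity filter and variable-gene selection",
                 ncol(aug_f)), verbose = cfg$verbose)

  ## --- preliminary score and doublet-count estimate -----------------------
  m_col <- log_standardize(aug_f, axis = "columns", log = FALSE)
  s <- preliminary_knn_scores(m_col, aug$labels, k = cfg$prelim_k,
                              n_pcs = cfg$n_pcs)
  nd_hat <- estimate_num_doublets(s, aug$labels, cfg$quantile_cut)
  dv_msg(sprintf("estimated %d doublets among %d input cells", nd_hat, n),
         verbose = cfg$verbose)
  if (nd_hat < 1L) {
    dv_stop(paste0("estimated doublet count is zero: the preliminary score ",
                   "separates simulated doublets completely from input cells"),
            "dv_no_doublets")
  }

  sim_scores <- s[aug$labels == 1L]
  keep_sim <- subsample_doublets(sim_scores, nd_hat,
                                 rng_seed = derive_seed(cfg$rng_seed, 2L))
  rows_keep <- c(seq_len(n), n + keep_sim)
  counts_red <- count_matrix(unclass(aug_f)[rows_keep, , drop = FALSE])
  labels_red <- aug$labels[rows_keep]
  parents_red <- aug$parents[keep_sim, , drop = FALSE]
  s_red <- s[rows_keep]

  ## --- clustering and homotypic exclusion ---------------------------------
  m_rows <- log_standardize(counts_red, axis = "rows", log = TRUE)
  clusters <- cluster_cells(m_rows, small_threshold = cfg$small_threshold,
                            meta_fraction = cfg$meta_fraction,
                            n_pcs = cfg$n_pcs, knn_k = cfg$knn_k,
                            resolution = cfg$resolution,
                            rng_seed = derive_seed(cfg$rng_seed, 3L))
  dv_msg(sprintf("Leiden found %d clusters", clusters$n_clusters),
         verbose = cfg$verbose)
  het <- exclude_homotypic(parents_red, clusters)
  if (!any(het)) {
    dv_stop(paste0("doublet simulation collapsed: every simulated doublet is ",
                   "homotypic (all parents share one cluster); cannot form a ",
                   "positive set for doublet annotation"),
            "dv_homotypic_collapse")
  }
  dv_msg(sprintf("homotypic exclusion: kept %d of %d simulated doublets",
                 sum(het), length(het)), verbose = cfg$verbose)
  final_keep <- c(seq_len(n), n + which(het))
  counts_fin <- count_matrix(unclass(counts_red)[final_keep, , drop = FALSE])
  labels_fin <- labels_red[final_keep]
  s_fin <- s_red[final_keep]
  labs_fin <- clusters$assignments[final_keep]
  labs_fin <- as.integer(factor(labs_fin, levels = sort(unique(labs_fin)))) - 1L
  n_clusters_fin <- length(unique(labs_fin))

  ## --- cluster-aware VAE embedding ----------------------------------------
  m_vae <- log_standardize(counts_fin, axis = "columns", log = TRUE)
  vcfg <- cfg$vae
  vcfg$rng_seed <- derive_seed(cfg$rng_seed, 4L)
  model <- build_vae(ncol(m_vae), n_clusters_fin, vcfg)
  model <- train_vae(model, m_vae, labs_fin, verbose = FALSE)
  dv_msg(sprintf("VAE trained for %d epochs (best epoch %d)",
                 nrow(model$history), model$best_epoch), verbose = cfg$verbose)
  z <- embed_vae(model, m_vae)

  ## --- PU bagging ----------------------------------------------------------
  zbar <- cbind(z, prelim_score = s_fin)
  pcfg <- cfg$pu
  pcfg$rng_seed <- derive_seed(cfg$rng_seed, 5L)
  pu <- pu_bagging(zbar, labels_fin, pcfg)
  dv_msg(sprintf("PU bagging: %d x %d classifiers, %d epochs each",
                 pcfg$n_reps, pcfg$n_folds, pu$epochs), verbose = cfg$verbose)

  ## --- calling --------------------------------------------------------------
  exp_d <- expected_doublets(n, cfg$expected_doublets)
  call_res <- NULL
  calls <- rep(NA, n)
  if (isTRUE(cfg$call)) {
    call_res <- call_doublets(pu$xi, pu$xi_pos, exp_d$mu, exp_d$sigma,
                              verbose = cfg$verbose)
    calls <- call_res$calls
    dv_msg(sprintf("called %d doublets at threshold %.4f",
                   call_res$n_called, call_res$threshold),
           verbose = cfg$verbose)
  }

  structure(list(
    scores = tibble::tibble(barcode = rownames(x),
                            doublet_score = pu$xi,
                            doublet_call = calls),
    call = call_res,
    nd_hat = nd_hat,
    mu = exp_d$mu, sigma = exp_d$sigma,
    latent = z[seq_len(n), , drop = FALSE],
    latent_all = z,
    labels_aug = labels_fin,
    prelim_scores = s_fin,
    xi_sim = pu$xi_pos,
    clusters = labs_fin,
    vae_history = model$history,
    vae_input = m_vae,
    genes_used = colnames(counts_fin),
    config = cfg,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "doublet_result")
}

#' @export
print.doublet_result <- function(x, ...) {
  cat(sprintf("<doublet_result> %d barcodes; estimated %d doublets",
              nrow(x$scores), x$nd_hat))
  if (!is.null(x$call)) {
    cat(sprintf("; called %d at threshold %.4f", x$call$n_called,
                x$call$threshold))
  }
  cat(sprintf(" (%.1f s)\n", x$runtime_s))
  print(utils::head(x$scores, 5L))
  invisible(x)
}
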