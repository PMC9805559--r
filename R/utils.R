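#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rnorm runif rbinom rnbinom rlnorm var dnorm
#'   kmeans prcomp wilcox.test
#' @importFrom utils head read.csv write.csv
NULL

# Stops with a classed condition so callers/tests can match on class.
dv_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "doubletvae_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

dv_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[doubletvae] ", ...)
}

#' Project a matrix onto its leading principal components
#'
#' Exact PCA by eigendecomposition of the smaller Gram matrix (features
#' Gram when p <= n, observation Gram otherwise), so the cost is governed
#' by min(n, p) and the result is deterministic. Columns are centered but
#' not rescaled; use [log_standardize()] upstream when scaling is wanted.
#'
#' @param x numeric matrix (observations in rows).
#' @param n_pcs number of components to keep; silently truncated to
#'   `min(n_pcs, nrow(x) - 1, ncol(x))` with a warning when fewer rows than
#'   requested components are available.
#' @return matrix of principal-component scores (`nrow(x)` x kept components).
#' @keywords internal
pca_project <- function(x, n_pcs = 30L) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  keep <- min(n_pcs, n - 1L, p)
  if (keep < n_pcs) {
    warning(sprintf("reducing number of principal components from %d to %d (matrix is %d x %d)",
                    n_pcs, keep, n, p))
  }
  keep <- max(keep, 1L)
  xc <- sweep(x, 2L, colMeans(x), "-")
  if (p <= n) {
    g <- crossprod(xc)                       # p x p
    e <- eigen(g, symmetric = TRUE)
    v <- e$vectors[, seq_len(keep), drop = FALSE]
    scores <- xc %*% v
  } else {
    g <- tcrossprod(xc)                      # n x n
    e <- eigen(g, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(keep)], 0)
    u <- e$vectors[, seq_len(keep), drop = FALSE]
    scores <- u %*% diag(sqrt(lam), keep)
  }
  # fix component signs so repeated runs agree: largest-magnitude loading > 0
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(ncol(scores))))
  scores
}

#' Exact k-nearest neighbours (Euclidean), self excluded
#'
#' Blockwise brute-force search; ties broken by row index so results are
#' reproducible. Intended for the moderate sizes this package works at.
#'
#' @param x numeric matrix of coordinates (rows = points).
#' @param k neighbours per point, `1 <= k < nrow(x)`.
#' @param block rows processed per block (memory/speed trade-off).
#' @return integer matrix `nrow(x)` x `k` of neighbour row indices, nearest
#'   first.
#' @keywords internal
knn_index <- function(x, k, block = 1024L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k >= 1L, k < n)
  sq <- rowSums(x * x)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    # squared distances of block rows to all rows
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    for (r in seq_along(idx)) {
      i <- idx[r]
      d <- d2[r, ]
      d[i] <- Inf
      ord <- order(d, seq_len(n))[seq_len(k)]
      out[i, ] <- ord
    }
  }
  out
}

# sample-SD (n - 1) standardization of columns (or rows), the scale()
# convention; constant slices -> 0
standardize_mat <- function(x, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  if (axis == "rows") return(t(standardize_mat(t(x), "columns")))
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  s <- if (n > 1L) sqrt(colSums(xc * xc) / (n - 1L)) else rep(0, ncol(x))
  const <- s <= 0 | !is.finite(s)
  s[const] <- 1
  out <- sweep(xc, 2L, s, "/")
  out[, const] <- 0
  out
}

# derive a stream-specific 32-bit seed from the global seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + stream * 7919L
}
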