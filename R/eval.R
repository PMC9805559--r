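#' Average precision (area under the precision-recall curve)
#'
#' Step-wise average precision: items are ranked by decreasing score,
#' thresholds are grouped at distinct score values (ties enter together),
#' and `AP = sum over thresholds of (R_i - R_{i-1}) * P_i`. The preferred
#' metric here because doublets are rare and the classes are imbalanced.
#'
#' @param scores numeric scores (higher = more doublet-like).
#' @param truth logical or 0/1 vector; must contain both classes.
#' @return average precision in [0, 1].
#' @export
average_precision <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  if (!any(truth) || all(truth)) {
    dv_stop("truth must contain both doublets and singlets",
            "dv_validation_error")
  }
  ord <- order(-scores)
  sc <- scores[ord]
  tr <- truth[ord]
  # group tied scores: evaluate at the last index of each distinct value
  last <- which(!duplicated(sc, fromLast = TRUE))
  tp <- cumsum(tr)[last]
  fp <- cumsum(!tr)[last]
  precision <- tp / (tp + fp)
  recall <- tp / sum(truth)
  sum(diff(c(0, recall)) * precision)
}

#' Leave-one-out knn label accuracy in two representations
#'
#' Trains nothing: each point is classified by majority vote of its k
#' nearest neighbours (Euclidean, self excluded) among the remaining
#' points, once in the input representation and once in the latent one.
#' Used to check that the latent embedding preserves local doublet-label
#' structure.
#'
#' @param m_input matrix in input space (rows = cells).
#' @param z matrix in latent space, row-aligned with `m_input`.
#' @param truth logical doublet labels.
#' @param k neighbours (default 5; odd values avoid vote ties, an exact
#'   half-split predicts singlet).
#' @return list with `accuracy_input` and `accuracy_latent`.
#' @export
knn_label_preservation <- function(m_input, z, truth, k = 5L) {
  truth <- as.logical(truth)
  stopifnot(nrow(m_input) == length(truth), nrow(z) == length(truth))
  loo_acc <- function(x) {
    nn <- knn_index(as.matrix(x), k)
    votes <- rowMeans(matrix(truth[nn], nrow(nn), ncol(nn)))
    mean((votes > 0.5) == truth)
  }
  list(accuracy_input = loo_acc(m_input), accuracy_latent = loo_acc(z))
}

#' Fraction of singlets in each true doublet's neighbourhood
#'
#' For every true doublet, the fraction of its k nearest neighbours (over
#' all cells, self excluded) that are singlets. Doublets that mix heavily
#' with singlets — typically homotypic ones — score high and are the ones
#' annotation methods tend to miss.
#'
#' @param z embedding matrix (rows = cells).
#' @param truth logical doublet labels; at least one TRUE.
#' @param k neighbours (default 5).
#' @return numeric vector, one singlet-fraction per true doublet (in row
#'   order of the doublets).
#' @export
singlet_fraction_neighborhood <- function(z, truth, k = 5L) {
  truth <- as.logical(truth)
  stopifnot(nrow(z) == length(truth))
  if (!any(truth)) {
    dv_stop("no true doublets present", "dv_validation_error")
  }
  nn <- knn_index(as.matrix(z), k)
  singlet <- !truth
  frac <- rowMeans(matrix(singlet[nn], nrow(nn), ncol(nn)))
  frac[truth]
}
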