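## Class-imbalance treatments: minority oversampling, class-distribution
## reverse loss re-weighting, and the per-sample gradient penalty driven by
## pairwise gradient cosine similarity.

#' Cross-entropy loss
#'
#' `-sum(y*log(p) + (1-y)*log(1-p))` over the batch, averaged by default
#' (`reduction = "sum"` gives the plain sum). Predicted probabilities are
#' clamped to `[eps, 1-eps]` before taking logs. Optional per-class weights
#' implement loss re-weighting.
#'
#' @param p_hat Predicted probability of the positive class, per sample.
#' @param y Binary labels (0/1).
#' @param class_weights Optional length-2 positive vector `(w0, w1)`.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @param eps Clamping constant.
#' @return Scalar loss.
#' @export
ce_loss <- function(p_hat, y, class_weights = NULL, reduction = c("mean", "sum"),
                    eps = 1e-7) {
  reduction <- match.arg(reduction)
  if (length(p_hat) != length(y)) stop("length mismatch")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  p <- pmin(pmax(p_hat, eps), 1 - eps)
  li <- -(y * log(p) + (1 - y) * log(1 - p))
  if (!is.null(class_weights)) {
    if (length(class_weights) != 2 || any(class_weights <= 0))
      stop("class_weights must be two positive numbers")
    li <- li * class_weights[y + 1]
  }
  if (reduction == "mean") mean(li) else sum(li)
}

#' Oversample the minority class to balance an epoch
#'
#' Returns a shuffled index sequence containing every majority-class sample
#' once and the minority class resampled with replacement up to the majority
#' count, so the two classes contribute equally per epoch. Uses the current
#' RNG stream.
#'
#' @param labels Binary label vector.
#' @return Integer index vector of length `2 * max(class count)`.
#' @export
oversample_indices <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  i0 <- which(labels == 0); i1 <- which(labels == 1)
  if (length(i0) == 0 || length(i1) == 0)
    stop("both classes must be present to oversample")
  n <- max(length(i0), length(i1))
  up <- function(ii) if (length(ii) == n) ii else
    c(ii, ii[sample.int(length(ii), n - length(ii), replace = TRUE)])
  idx <- c(up(i0), up(i1))
  idx[sample.int(length(idx))]
}

#' Class-distribution reverse weights
#'
#' Per-class loss multipliers proportional to inverse class frequency
#' (lower weight for the head class, higher for the tail class), normalized
#' to average 1.
#'
#' @param class_counts Length-2 positive counts `(n0, n1)`.
#' @return Length-2 numeric weights `(w0, w1)` with mean 1.
#' @export
reverse_weights <- function(class_counts) {
  if (length(class_counts) != 2 || any(class_counts <= 0))
    stop("need two positive class counts")
  w <- 1 / class_counts
  w / mean(w)
}

#' Pairwise cosine similarity of per-sample gradients
#'
#' `cos(theta_ij) = g_i . g_j / (|g_i| |g_j|)`. Zero-norm gradients are
#' assigned similarity 0 against everything (so they are never penalized);
#' the diagonal is 1 for nonzero gradients.
#'
#' @param G Matrix (n x p); row i is sample i's flattened gradient.
#' @return Symmetric n x n matrix with entries in \[-1, 1\].
#' @export
cosine_similarity_matrix <- function(G) {
  if (!is.matrix(G)) G <- rbind(G)
  if (any(!is.finite(G))) stop("gradients must be finite")
  nrm <- sqrt(rowSums(G * G))
  S <- tcrossprod(G)
  denom <- outer(nrm, nrm)
  S <- ifelse(denom > 0, S / pmax(denom, .Machine$double.xmin), 0)
  S <- pmin(pmax(S, -1), 1)
  diag(S) <- ifelse(nrm > 0, 1, 0)
  S
}

#' Gradient-penalty shrink factors
#'
#' Sample i receives factor `lambda` when its gradient's cosine similarity
#' to any other sample's gradient exceeds `epsilon` (the near-duplicate test
#' excludes the diagonal), and factor 1 otherwise. With `rule = "power"` the
#' factor is `lambda^k` where k is the number of above-threshold partners.
#'
#' @param S Similarity matrix from [cosine_similarity_matrix()].
#' @param epsilon Similarity threshold, in (0, 1). Default 0.9 targets the
#'   near-identical gradients produced by oversampled duplicates.
#' @param lambda Shrink constant in (0, 1\]; default 0.5.
#' @param rule `"flat"` (default) or `"power"`.
#' @return Numeric vector of factors `f_i` in (0, 1\].
#' @export
penalty_factors <- function(S, epsilon = 0.9, lambda = 0.5,
                            rule = c("flat", "power")) {
  rule <- match.arg(rule)
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("epsilon must be in (0,1)")
  if (!is.finite(lambda) || lambda <= 0 || lambda > 1)
    stop("lambda must be in (0,1]")
  Soff <- S
  diag(Soff) <- -Inf
  k <- rowSums(Soff > epsilon)
  if (rule == "flat") ifelse(k > 0, lambda, 1) else lambda^k
}

#' Penalized gradient aggregation
#'
#' Scales each sample's gradient by its penalty factor before averaging:
#' `(1/n) * sum_i f_i g_i`. With all factors 1 this is exactly the
#' unpenalized mean batch gradient.
#'
#' @param G Matrix (n x p) of per-sample flattened gradients.
#' @param f Factors from [penalty_factors()], length n.
#' @return Numeric vector of length p.
#' @export
apply_gradient_penalty <- function(G, f) {
  if (!is.matrix(G)) G <- rbind(G)
  if (length(f) != nrow(G)) stop("one factor per sample required")
  colMeans(G * f)
}
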