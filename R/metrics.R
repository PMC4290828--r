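# Prediction-performance metrics and the T-index transferability statistic.

#' Classification accuracy
#'
#' @param pred,truth equal-length 0/1 vectors.
#' @return fraction of correct predictions.
#' @export
binaryAccuracy <- function(pred, truth) {
  if (length(pred) == 0) stop("empty prediction vector")
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  stopifnot(all(pred %in% c(0, 1)), all(truth %in% c(0, 1)))
  mean(pred == truth)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counted 1/2. Computed from mid-ranks, so it
#' is invariant under strictly monotone score transforms.
#'
#' @param scores numeric scores, larger = more class-1-like.
#' @param truth 0/1 labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(truth %in% c(0, 1)))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa for two prediction vectors
#'
#' Chance-corrected per-sample agreement, \eqn{\kappa = (p_o - p_e)/(1 -
#' p_e)} with the expected agreement from the marginal products. When both
#' raters are degenerate on the same single category (\eqn{p_e = 1}) the
#' statistic is defined as 0, with a warning.
#'
#' @param pred1,pred2 equal-length label vectors.
#' @return kappa in [-1, 1].
#' @export
cohenKappa <- function(pred1, pred2) {
  if (length(pred1) == 0) stop("empty prediction vectors")
  if (length(pred1) != length(pred2)) stop("prediction lengths differ")
  lv <- sort(unique(c(pred1, pred2)))
  t1 <- factor(pred1, levels = lv)
  t2 <- factor(pred2, levels = lv)
  n <- length(pred1)
  po <- mean(pred1 == pred2)
  pe <- sum((table(t1) / n) * (table(t2) / n))
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("degenerate marginals (p_e = 1); kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Agreement bands for kappa values
#'
#' The qualitative bands used to read per-sample agreement: fair
#' (0.2, 0.4], moderate (0.4, 0.6], substantial (0.6, 0.8], perfect (> 0.8);
#' values at or below 0.2 are labelled slight.
#'
#' @param kappa numeric vector of kappa values.
#' @return character vector of band labels.
#' @export
kappaBand <- function(kappa) {
  cut(kappa, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
      labels = c("slight", "fair", "moderate", "substantial", "perfect"),
      right = TRUE) |> as.character()
}

#' T-index transferability score
#'
#' Combines the mean accuracy of the source-platform models, the mean
#' source-minus-target accuracy difference, and its dispersion:
#' \deqn{T = \bar P^A \left[1 - \frac{\overline{P^A - P^B}}{e^{-s.d.}}\right]}
#' where the standard deviation of the paired differences uses the n-1
#' denominator (set \code{sdType = "population"} for the n denominator).
#' Identical accuracy vectors give T = mean source accuracy. The raw value
#' can exceed 1 when the counterpart models outperform the source models, so
#' a [0,1]-clipped companion is returned alongside the raw value.
#'
#' @param pA per-model accuracies of the source-platform models (length >= 2).
#' @param pB matched accuracies of the counterpart models.
#' @param sdType \code{"sample"} (n-1, default) or \code{"population"}.
#' @return list with elements \code{t} (raw) and \code{tClipped}.
#' @examples
#' tIndex(c(0.9, 0.8), c(0.7, 0.8))$t  # ~0.752
#' @export
tIndex <- function(pA, pB, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  if (length(pA) != length(pB)) stop("paired accuracy vectors differ in length")
  if (length(pA) < 2) stop("T-index needs N >= 2 (s.d. undefined)")
  stopifnot(all(pA >= 0 & pA <= 1), all(pB >= 0 & pB <= 1))
  d <- pA - pB
  s <- stats::sd(d)
  if (sdType == "population") s <- s * sqrt((length(d) - 1) / length(d))
  t <- mean(pA) * (1 - mean(d) / exp(-s))
  list(t = t, tClipped = min(1, max(0, t)))
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values numeric vector (non-empty).
#' @param B number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return numeric c(lo, hi).
#' @export
bootstrapCI <- function(values, B = 1000, level = 0.95, seed = 1) {
  if (length(values) == 0) stop("empty value vector")
  n <- length(values)
  means <- withSeed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    colMeans(matrix(values[idx], nrow = n))
  })
  a <- (1 - level) / 2
  unname(stats::quantile(means, c(a, 1 - a), type = 7))
}
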