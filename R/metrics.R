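# Training objective and evaluation metrics: pixelwise binary
# cross-entropy, the over-images batch loss, probability thresholding, the
# Jaccard index, and the fold-aggregation / comparative-increase report
# arithmetic.

BCE_EPS <- 1e-7

checkMaskPair <- function(a, b, what = "metric") {
  da <- dim(a); db <- dim(b)
  if (is.null(da)) da <- length(a)
  if (is.null(db)) db <- length(b)
  if (!identical(as.integer(da), as.integer(db)))
    stopf("%s: shape mismatch (%s vs %s)", what,
          paste(da, collapse = "x"), paste(db, collapse = "x"))
}

#' Pixelwise binary cross-entropy
#'
#' For a binary ground-truth mask \eqn{B} with values \eqn{b_p} and a
#' predicted probability map \eqn{\hat B} with values \eqn{\hat b_p},
#' computes \eqn{\sum_p -(b_p \log \hat b_p + (1-b_p)\log(1-\hat b_p))}
#' (`reduction = "sum"`) or its per-pixel mean. Predictions are clamped to
#' \eqn{[\epsilon, 1-\epsilon]} with \eqn{\epsilon = 10^{-7}} before the
#' logarithms. Sum mode equals mean mode times the pixel count exactly.
#'
#' @param mask binary array (values 0/1).
#' @param pred probability array of the same shape, values in \[0, 1\].
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return non-negative scalar loss.
#' @examples
#' pixelBce(1, 0.5, "sum")   # log(2)
#' @export
pixelBce <- function(mask, pred, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  checkMaskPair(mask, pred, "pixelBce")
  if (any(mask != 0 & mask != 1))
    stopf("pixelBce: mask must be strictly binary")
  p <- pmin(pmax(as.numeric(pred), BCE_EPS), 1 - BCE_EPS)
  b <- as.numeric(mask)
  tot <- -sum(b * log(p) + (1 - b) * log(1 - p))
  if (reduction == "sum") tot else tot / length(p)
}

#' Batch loss: mean cross-entropy over images
#'
#' The training objective over a batch of m images is the arithmetic mean
#' of the per-image pixelwise binary cross-entropies.
#'
#' @param masks list of m binary masks.
#' @param preds list of m probability maps, aligned with `masks`.
#' @param reduction per-image reduction, as in [pixelBce()].
#' @return non-negative scalar.
#' @export
batchLoss <- function(masks, preds, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (length(masks) < 1) stopf("batchLoss: empty batch")
  if (length(masks) != length(preds))
    stopf("batchLoss: %d masks but %d predictions", length(masks),
          length(preds))
  mean(vapply(seq_along(masks), function(i)
    pixelBce(masks[[i]], preds[[i]], reduction), numeric(1)))
}

#' Threshold a probability map
#'
#' A pixel is assigned to the foreground iff its probability is greater
#' than or equal to the threshold (ties go to foreground).
#'
#' @param pred probability array.
#' @param threshold cut-off in (0, 1); default 0.5.
#' @return binary array (0/1) of the same shape.
#' @export
binarize <- function(pred, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stopf("binarize: threshold must lie strictly in (0, 1)")
  out <- (pred >= threshold) + 0
  dim(out) <- dim(pred)
  out
}

#' Jaccard index (intersection over union)
#'
#' \eqn{JI = |X \cap Y| / |X \cup Y|} for two binary masks of equal shape.
#' When both masks are empty the index is defined as 1 (two identical,
#' empty segmentations).
#'
#' @param x,y binary arrays of equal shape.
#' @return scalar in \[0, 1\].
#' @examples
#' jaccard(c(1, 1, 0), c(1, 0, 1))   # 1/3
#' @export
jaccard <- function(x, y) {
  checkMaskPair(x, y, "jaccard")
  xs <- x != 0
  ys <- y != 0
  uni <- sum(xs | ys)
  if (uni == 0) return(1)
  sum(xs & ys) / uni
}

#' Aggregate per-fold scores
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' per-fold Jaccard percentages, the "mean +/- std" of a cross-validation
#' report.
#'
#' @param values numeric vector of at least two per-fold values.
#' @return named numeric `c(mean =, sd =)`.
#' @examples
#' aggregateFolds(c(74.11, 72.67, 73.89, 75.22, 76.07))  # mean 74.392
#' @export
aggregateFolds <- function(values) {
  if (length(values) < 2)
    stopf("aggregateFolds: need at least 2 values, got %d", length(values))
  c(mean = mean(values), sd = stats::sd(values))
}

#' Comparative increase in performance
#'
#' The difference, in percentage points, between the proposed model's mean
#' Jaccard percentage and the baseline's.
#'
#' @param proposedMean,traditionalMean mean Jaccard percentages.
#' @return `proposedMean - traditionalMean`.
#' @examples
#' comparativeIncrease(83.1567, 72.9190)   # 10.2377
#' @export
comparativeIncrease <- function(proposedMean, traditionalMean) {
  if (!is.finite(proposedMean) || !is.finite(traditionalMean))
    stopf("comparativeIncrease: inputs must be finite")
  proposedMean - traditionalMean
}
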