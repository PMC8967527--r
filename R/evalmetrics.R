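# Segmentation and recognition metrics.
#
# Segmentation: for ground truth Eg and segmentation Es,
#   Md = |Eg ∩ Es| / |Eg ∪ Es| * 100       (Jaccard overlap, %)
#   Vd = |Es ⊕ Eg| / |Es| * 100            (over-segmentation fraction, %)
#   Ud = |Eg ⊕ Es| / |Eg| * 100            (under-segmentation fraction, %)
#   CM = (Md + (100 - Vd) + (100 - Ud)) / 3
# Vd and Ud may exceed 100 for gross mismatches (the XOR can be larger than
# either mask); they are reported as computed, not clamped.
#
# Recognition: SEN = TP/(TP+FN), SPE = TN/(TN+FP) and a misclassified
# fraction FPF = (FP+FN)/total, all in percent. FPF is algebraically
# 100 - accuracy.

#' Segmentation overlap scores (Md, Vd, Ud, CM)
#'
#' @param Eg logical array, the ground-truth mask (nonempty).
#' @param Es logical array, the segmented mask (nonempty), same shape.
#' @return named numeric vector with elements `Md`, `Vd`, `Ud`, `CM`, in
#'   percent. Identical masks give `c(100, 0, 0, 100)`.
#' @examples
#' Eg <- array(FALSE, c(10, 10, 1)); Eg[1:5, , ] <- TRUE
#' segScores(Eg, Eg)
#' @export
segScores <- function(Eg, Es) {
  if (!identical(dim(Eg), dim(Es))) stop("masks must have the same shape")
  Eg <- Eg > 0; Es <- Es > 0
  nG <- sum(Eg); nS <- sum(Es)
  if (nG == 0) stop("ground-truth mask is empty; Md and Ud are undefined")
  if (nS == 0) stop("segmented mask is empty; Vd is undefined")
  inter <- sum(Eg & Es)
  xor <- nG + nS - 2 * inter
  Md <- inter / (nG + nS - inter) * 100
  Vd <- xor / nS * 100
  Ud <- xor / nG * 100
  CM <- (Md + (100 - Vd) + (100 - Ud)) / 3
  c(Md = Md, Vd = Vd, Ud = Ud, CM = CM)
}

#' Soft Dice loss
#'
#' \eqn{1 - 2\sum_i p_i g_i / (\sum_i p_i^2 + \sum_i g_i^2 + \epsilon)} with
#' smoothing \eqn{\epsilon = 1} so the loss is defined (and 0-valued in the
#' limit) when both maps are empty.
#'
#' @param p numeric array of probabilities in (0,1) (binary values allowed).
#' @param g binary array of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss in `[0, 1]`.
#' @examples
#' diceLoss(c(0.8, 0.2), c(1, 0))  # 0.40298...
#' @export
diceLoss <- function(p, g, eps = 1) {
  if (!identical(dim(p), dim(g)) && length(p) != length(g)) {
    stop("p and g must have the same shape")
  }
  1 - 2 * sum(p * g) / (sum(p^2) + sum(g^2) + eps)
}

#' Recognition scores from a confusion table
#'
#' @param TP,FP,TN,FN nonnegative confusion counts.
#' @return named numeric vector `SEN`, `SPE`, `FPF` in percent, where
#'   `FPF = (FP + FN) / (TP + FP + TN + FN) * 100` (the misclassified
#'   fraction, i.e. 100 minus accuracy).
#' @examples
#' recognitionScores(TP = 9, FP = 2, TN = 8, FN = 1)  # SEN 90, SPE 80, FPF 15
#' @export
recognitionScores <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  if (TP + FN == 0) stop("SEN undefined: no positive samples (TP+FN = 0)")
  if (TN + FP == 0) stop("SPE undefined: no negative samples (TN+FP = 0)")
  tot <- TP + FP + TN + FN
  c(SEN = TP / (TP + FN) * 100,
    SPE = TN / (TN + FP) * 100,
    FPF = (FP + FN) / tot * 100)
}

#' ROC curve and area by the trapezoid rule
#'
#' Sweeps the decision threshold over the distinct score values (ties share
#' one point) and returns monotone (FPR, TPR) points from (0,0) to (1,1)
#' plus the trapezoidal area under the curve.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels (both classes must be present).
#' @return list with `points` (data frame of `fpr`, `tpr`) and `auc`.
#' @examples
#' rocCurve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc  # 1
#' @export
rocCurve <- function(scores, labels) {
  labels <- labels > 0
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to form a ROC curve")
  }
  np <- sum(labels); nn <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(!l)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tpr <- c(0, tp[keep] / np)
  fpr <- c(0, fp[keep] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}
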