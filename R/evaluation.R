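.checkBinary <- function(x, what) {
  if (!all(x %in% c(0, 1))) stop("'", what, "' must be strictly 0/1-valued")
}

#' Pixel confusion counts within the field of view
#'
#' Counts true/false positives/negatives over `fov == 1` pixels only
#' (vessel = positive class). The four counts always sum to the FOV pixel
#' count.
#'
#' @param pred,gt,fov 0/1 matrices of identical dimensions.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusionCounts <- function(pred, gt, fov) {
  if (!all(dim(pred) == dim(gt)) || !all(dim(pred) == dim(fov)))
    stop("'pred', 'gt' and 'fov' dimensions differ")
  .checkBinary(pred, "pred"); .checkBinary(gt, "gt"); .checkBinary(fov, "fov")
  sel <- fov == 1
  p <- pred[sel]; g <- gt[sel]
  c(TP = as.integer(sum(p == 1 & g == 1)),
    TN = as.integer(sum(p == 0 & g == 0)),
    FP = as.integer(sum(p == 1 & g == 0)),
    FN = as.integer(sum(p == 0 & g == 1)))
}

#' Accuracy, sensitivity, specificity and precision
#'
#' The four standard ratios of a pixel-level confusion matrix:
#' `Acc = (TP+TN)/(TP+FP+TN+FN)`, `Sen = TP/(TP+FN)`, `Spc = TN/(FP+TN)`,
#' `Prc = TP/(FP+TP)`. A ratio with zero denominator is reported as `NA`
#' (undefined), never coerced to 0 or 1.
#'
#' @param counts Named vector with elements `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `c(acc, sen, spc, prc)`.
#' @examples
#' segMetrics(c(TP = 40, TN = 50, FP = 5, FN = 5))
#' @export
segMetrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(acc = ratio(tp + tn, total),
    sen = ratio(tp, tp + fn),
    spc = ratio(tn, fp + tn),
    prc = ratio(tp, fp + tp))
}

.degenerateCheck <- function(gt, fov) {
  g <- gt[fov == 1]
  if (all(g == 1))
    stop("ground truth within FOV is all vessel (positive): FPR undefined")
  if (all(g == 0))
    stop("ground truth within FOV is all background (negative): TPR undefined")
}

#' ROC points over a global-threshold sweep
#'
#' For every threshold `tau` in the grid, binarizes at `prob >= tau` and
#' computes `TPR = TP/(TP+FN)` and `FPR = FP/(FP+TN)` within the FOV. The
#' points are sorted by FPR (then TPR) with (0, 0) and (1, 1) appended, so
#' they bound a proper curve for trapezoidal integration.
#'
#' @param prob Probability matrix with values in `[0, 1]`.
#' @param gt,fov 0/1 matrices.
#' @param taus Increasing threshold grid (default `seq(0.01, 0.99, 0.01)`).
#' @return Two-column matrix `(FPR, TPR)`.
#' @export
rocSweep <- function(prob, gt, fov, taus = seq(0.01, 0.99, by = 0.01)) {
  if (length(taus) == 0 || is.unsorted(taus, strictly = TRUE))
    stop("'taus' must be a non-empty increasing grid")
  if (min(prob) < 0 || max(prob) > 1) stop("'prob' must lie in [0, 1]")
  .degenerateCheck(gt, fov)
  sel <- fov == 1
  p <- prob[sel]; g <- gt[sel]
  nPos <- sum(g == 1); nNeg <- sum(g == 0)
  pts <- t(vapply(taus, function(tau) {
    pred <- p >= tau
    c(fpr = sum(pred & g == 0) / nNeg, tpr = sum(pred & g == 1) / nPos)
  }, numeric(2)))
  pts <- rbind(pts, c(0, 0), c(1, 1))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  colnames(pts) <- c("FPR", "TPR")
  pts
}

#' Trapezoidal area under ROC points
#'
#' @param points Two-column `(FPR, TPR)` matrix sorted by FPR, containing
#'   (0, 0) and (1, 1), all values in `[0, 1]`.
#' @return The area, in `[0, 1]`.
#' @examples
#' aurocTrapezoid(rbind(c(0, 0), c(0, 1), c(1, 1)))   # 1
#' @export
aurocTrapezoid <- function(points) {
  if (!is.matrix(points) || ncol(points) != 2 || nrow(points) < 2)
    stop("'points' must be a matrix of at least two (FPR, TPR) rows")
  x <- points[, 1]; y <- points[, 2]
  if (min(points) < -1e-12 || max(points) > 1 + 1e-12)
    stop("ROC points must lie in [0, 1]")
  if (is.unsorted(x)) stop("ROC points must be sorted by FPR")
  if (abs(x[1]) > 1e-12 || abs(y[1]) > 1e-12 ||
      abs(x[length(x)] - 1) > 1e-12 || abs(y[length(y)] - 1) > 1e-12)
    stop("ROC points must start at (0,0) and end at (1,1)")
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Threshold-sensitivity table
#'
#' Computes accuracy, sensitivity, specificity and precision at every
#' threshold of the grid (one row per `tau`). Around the flat region of
#' this table -- empirically near `tau = 0.5` -- the choice of global
#' threshold barely moves the metrics, which is what justifies the default
#' operating point.
#'
#' @inheritParams rocSweep
#' @return Data frame with columns `tau`, `acc`, `sen`, `spc`, `prc`.
#' @export
tauSensitivity <- function(prob, gt, fov, taus = seq(0.01, 0.99, by = 0.01)) {
  if (length(taus) == 0 || is.unsorted(taus, strictly = TRUE))
    stop("'taus' must be a non-empty increasing grid")
  .degenerateCheck(gt, fov)
  rows <- lapply(taus, function(tau) {
    m <- segMetrics(confusionCounts((prob >= tau) * 1, gt, fov))
    data.frame(tau = tau, acc = m[["acc"]], sen = m[["sen"]],
               spc = m[["spc"]], prc = m[["prc"]])
  })
  do.call(rbind, rows)
}

#' Full evaluation of a probability map
#'
#' Bundles [confusionCounts()] and [segMetrics()] at the operating
#' threshold, the ROC sweep with its trapezoidal AUROC, and the
#' threshold-sensitivity table into one [EvalReport-class].
#'
#' @inheritParams rocSweep
#' @param tau Operating threshold for the headline metrics (default 0.5).
#' @return An [EvalReport-class].
#' @export
evaluateSegmentation <- function(prob, gt, fov, tau = 0.5,
                                 taus = seq(0.01, 0.99, by = 0.01)) {
  counts <- confusionCounts((prob >= tau) * 1, gt, fov)
  m <- segMetrics(counts)
  roc <- rocSweep(prob, gt, fov, taus)
  new("EvalReport", counts = counts, acc = m[["acc"]], sen = m[["sen"]],
      spc = m[["spc"]], prc = m[["prc"]], roc = roc,
      auroc = aurocTrapezoid(roc), tauTable = tauSensitivity(prob, gt, fov, taus))
}
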