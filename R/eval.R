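#' Match predicted cells to ground-truth cells
#'
#' Greedy one-to-one matching by descending intersection-over-union; pairs
#' whose IoU strictly exceeds \code{iouThreshold} (or equals 1) are
#' matches. The assignment also
#' records which truth cells were split across at least two predictions and
#' which predictions merge at least two truth cells, using a secondary
#' overlap floor of \code{minorOverlap} of the truth cell's area to tell
#' genuine fragments from incidental boundary overlap.
#'
#' @param pred,truth integer label matrices of identical shape.
#' @param iouThreshold IoU above which a pair is a correct segmentation
#'   (default 0.5).
#' @param minorOverlap secondary overlap floor as a fraction of the truth
#'   cell area (default 0.2).
#' @return a list of class \code{"wbcAssignment"}: \code{pairs} (all
#'   overlapping label pairs with their IoU), \code{matches},
#'   \code{unmatchedTruth}, \code{unmatchedPred}, \code{splitTruth},
#'   \code{mergedPred}, \code{nTruth}, \code{nPred}.
#' @export
matchRegions <- function(pred, truth, iouThreshold = 0.5,
                         minorOverlap = 0.2) {
  if (!identical(dim(pred), dim(truth)))
    stop("matchRegions: label masks must share one shape")
  stopifnot(iouThreshold > 0, iouThreshold <= 1)
  predL <- sort(setdiff(unique(as.vector(pred)), 0L))
  truthL <- sort(setdiff(unique(as.vector(truth)), 0L))
  areaP <- tabulate(pred[pred > 0], max(0L, pred))
  areaT <- tabulate(truth[truth > 0], max(0L, truth))
  sel <- pred > 0 & truth > 0
  if (any(sel)) {
    tab <- table(p = pred[sel], t = truth[sel])
    pairs <- as.data.frame(tab, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$Freq > 0, ]
    pairs$p <- as.integer(pairs$p)
    pairs$t <- as.integer(pairs$t)
    names(pairs)[3] <- "inter"
    pairs$iou <- pairs$inter /
      (areaP[pairs$p] + areaT[pairs$t] - pairs$inter)
    pairs$truthCover <- pairs$inter / areaT[pairs$t]
  } else {
    pairs <- data.frame(p = integer(), t = integer(),
                        inter = integer(), iou = numeric(),
                        truthCover = numeric())
  }
  # greedy one-to-one by descending IoU, deterministic tie-break; a match
  # must exceed the threshold strictly (a cell covered half-and-half by two
  # predictions is broken, not correct), except that a perfect overlap
  # always matches
  ord <- order(-pairs$iou, pairs$p, pairs$t)
  usedP <- integer(); usedT <- integer()
  mrows <- integer()
  for (i in ord) {
    if (pairs$iou[i] <= iouThreshold && pairs$iou[i] < 1) break
    if (pairs$p[i] %in% usedP || pairs$t[i] %in% usedT) next
    usedP <- c(usedP, pairs$p[i])
    usedT <- c(usedT, pairs$t[i])
    mrows <- c(mrows, i)
  }
  matches <- pairs[mrows, c("p", "t", "iou")]
  big <- pairs[pairs$truthCover >= minorOverlap, , drop = FALSE]
  splitTruth <- as.integer(names(which(table(big$t) >= 2)))
  mergedPred <- as.integer(names(which(table(big$p) >= 2)))
  structure(list(
    pairs = pairs, matches = matches,
    unmatchedTruth = setdiff(truthL, matches$t),
    unmatchedPred = setdiff(predL, matches$p),
    splitTruth = splitTruth, mergedPred = mergedPred,
    nTruth = length(truthL), nPred = length(predL)),
    class = "wbcAssignment")
}

#' Count segmentation outcomes
#'
#' Correct cells (TP) are the matches; missed or broken truth cells are FN;
#' spurious predictions (red cells, debris, fragments) are FP. A truth cell
#' split across two or more predictions counts one oversegmentation; a
#' prediction covering two or more truth cells counts one
#' undersegmentation.
#'
#' @param assignment result of \code{\link{matchRegions}}.
#' @return an \linkS4class{EvalReport}.
#' @export
countOutcomes <- function(assignment) {
  stopifnot(inherits(assignment, "wbcAssignment"))
  tp <- nrow(assignment$matches)
  fn <- length(assignment$unmatchedTruth)
  fp <- length(assignment$unmatchedPred)
  evalReport(tp, fp, fn,
             overseg = length(assignment$splitTruth),
             underseg = length(assignment$mergedPred))
}

#' Precision, recall and F-measure from outcome counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R); empty denominators give
#' 0 (the empty-success convention).
#'
#' @param tp,fp,fn non-negative counts.
#' @return named numeric vector \code{c(precision, recall, f1)}, fractions
#'   in [0, 1].
#' @examples
#' round(100 * fMeasure(1481, 10, 69)["recall"], 1)  # 95.5
#' @export
fMeasure <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Build an evaluation report from counts
#'
#' @param tp,fp,fn,overseg,underseg non-negative counts.
#' @return an \linkS4class{EvalReport}.
#' @export
evalReport <- function(tp, fp, fn, overseg = 0, underseg = 0) {
  f <- fMeasure(tp, fp, fn)
  new("EvalReport", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), overseg = as.integer(overseg),
      underseg = as.integer(underseg),
      precision = unname(f["precision"]), recall = unname(f["recall"]),
      f1 = unname(f["f1"]))
}

#' Evaluate a segmentation against ground truth
#'
#' Convenience wrapper: match regions, count outcomes.
#'
#' @param pred predicted label matrix or \linkS4class{SegmentationResult}.
#' @param truth truth label matrix or \linkS4class{SyntheticSmear}.
#' @param iouThreshold IoU for a correct segmentation.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateSegmentation <- function(pred, truth, iouThreshold = 0.5) {
  if (is(pred, "SegmentationResult")) pred <- wbcLabels(pred)
  if (is(truth, "SyntheticSmear")) truth <- wbcLabels(truth)
  countOutcomes(matchRegions(pred, truth, iouThreshold))
}
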