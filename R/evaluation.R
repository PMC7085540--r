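# Evaluation. Frame level: detection P/R/F1 under greedy IoU matching, and
# activity P/R/F1 under the largest-IoU rule with a minimum overlap.
# Track level: a track is a true positive when the fraction of its frames
# overlapping the ground-truth track at IoU >= alpha reaches theta; TPR% is
# the percentage of true-positive tracks over a test set.

# coerce DetectionSet / TrackSet / data frame to a plain box table
asBoxTable <- function(x) {
  if (is(x, "DetectionSet")) return(x@detections)
  if (is(x, "TrackSet")) return(x@assignments)
  as.data.frame(x)
}

#' Evaluate detections against ground truth (P/R/F1)
#'
#' Per frame, predictions and ground-truth boxes are matched greedily by
#' descending IoU; a match at IoU >= \code{detectionIoU} is a true
#' positive. Unmatched predictions are false positives, unmatched
#' ground-truth boxes false negatives.
#'
#' @param pred,gt detections ([DetectionSet-class] or data frame with
#'   \code{frame, x, y, w, h}).
#' @param detectionIoU IoU threshold for a true positive (default 0.5).
#' @return An [EvalReport-class].
#' @export
evalDetections <- function(pred, gt, detectionIoU = 0.5) {
  p <- asBoxTable(pred)
  g <- asBoxTable(gt)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (f in sort(unique(c(p$frame, g$frame)))) {
    pf <- p[p$frame == f, , drop = FALSE]
    gf <- g[g$frame == f, , drop = FALSE]
    if (nrow(pf) == 0L) { fn <- fn + nrow(gf); next }
    if (nrow(gf) == 0L) { fp <- fp + nrow(pf); next }
    iou <- outer(seq_len(nrow(pf)), seq_len(nrow(gf)),
                 Vectorize(function(i, j)
                   boxIoU(asBoxMatrix(pf[i, , drop = FALSE]),
                          asBoxMatrix(gf[j, , drop = FALSE]))))
    usedP <- logical(nrow(pf)); usedG <- logical(nrow(gf))
    repeat {
      iou[usedP, ] <- -1
      iou[, usedG] <- -1
      best <- which.max(iou)
      if (length(best) == 0L || iou[best] < detectionIoU) break
      ij <- arrayInd(best, dim(iou))
      usedP[ij[1]] <- TRUE; usedG[ij[2]] <- TRUE
      tp <- tp + 1L
    }
    fp <- fp + sum(!usedP)
    fn <- fn + sum(!usedG)
  }
  EvalReport(tp, fp, fn)
}

#' Evaluate per-frame active-subject predictions (P/R/F1)
#'
#' A frame is a true positive when a predicted active box exists, the
#' ground truth marks an active box, the prediction has the largest IoU
#' with the ground-truth active box among that frame's detected boxes, and
#' that IoU is at least \code{minActivityIoU}. A wrong or absent prediction
#' where ground truth exists counts as a false negative; a prediction in a
#' frame without ground truth counts as a false positive.
#'
#' @param predActive data frame \code{frame, x, y, w, h}: at most one
#'   predicted active box per frame (absent frame = no prediction).
#' @param gtActive data frame \code{frame, x, y, w, h}: the ground-truth
#'   active box per frame.
#' @param dets all detected boxes per frame (the candidate set for the
#'   largest-IoU rule); [DetectionSet-class] or data frame.
#' @param minActivityIoU minimum overlap for a true positive (default
#'   0.1).
#' @return An [EvalReport-class].
#' @export
evalFrameActivity <- function(predActive, gtActive, dets,
                              minActivityIoU = 0.1) {
  p <- asBoxTable(predActive)
  g <- asBoxTable(gtActive)
  d <- asBoxTable(dets)
  if (anyDuplicated(p$frame) > 0L)
    stop("more than one predicted active box in a frame")
  tp <- 0L; fp <- 0L; fn <- 0L
  for (f in sort(unique(c(p$frame, g$frame)))) {
    pf <- p[p$frame == f, , drop = FALSE]
    gf <- g[g$frame == f, , drop = FALSE]
    if (nrow(gf) == 0L) { if (nrow(pf) > 0L) fp <- fp + 1L; next }
    if (nrow(pf) == 0L) { fn <- fn + 1L; next }
    gbox <- asBoxMatrix(gf[1L, , drop = FALSE])
    iouPred <- boxIoU(asBoxMatrix(pf), gbox)
    df <- d[d$frame == f, , drop = FALSE]
    iouAll <- if (nrow(df) > 0L) boxIoU(asBoxMatrix(df), gbox) else numeric()
    largest <- length(iouAll) == 0L || iouPred >= max(iouAll) - 1e-12
    if (largest && iouPred >= minActivityIoU) tp <- tp + 1L else fn <- fn + 1L
  }
  EvalReport(tp, fp, fn)
}

#' Track-level true positive decision
#'
#' Over the frames of the evaluated track, \code{f(B) = 1} when the box
#' overlaps the ground-truth track's box of the same frame at IoU >=
#' \code{alpha} (frames where the ground truth is absent count 0). The
#' track is a true positive (returns 1) when the fraction of matching
#' frames over the track's length reaches \code{theta} (inclusive).
#'
#' @param track,gtTrack box tables (\code{frame, x, y, w, h}); a
#'   [TrackSet-class] plus an id can be subset with [trackBoxes()].
#' @param alpha per-frame IoU threshold (default 0.5).
#' @param theta minimum matching fraction (default 0.5).
#' @return 0 or 1.
#' @export
evalTrack <- function(track, gtTrack, alpha = 0.5, theta = 0.5) {
  tr <- asBoxTable(track)
  gt <- asBoxTable(gtTrack)
  if (nrow(tr) == 0L) stop("empty track")
  m <- match(tr$frame, gt$frame)
  f <- vapply(seq_len(nrow(tr)), function(i) {
    if (is.na(m[i])) return(0)
    as.numeric(boxIoU(asBoxMatrix(tr[i, , drop = FALSE]),
                      asBoxMatrix(gt[m[i], , drop = FALSE])) >= alpha)
  }, numeric(1))
  as.integer(sum(f) / nrow(tr) >= theta)
}

#' Percentage of true-positive tracks
#'
#' @param trackResults vector of 0/1 decisions from [evalTrack()] over a
#'   test set.
#' @return 100 times the mean.
#' @export
tprPercent <- function(trackResults) {
  if (length(trackResults) == 0L) stop("no track results")
  100 * mean(trackResults)
}

#' Extract one track's box table from a TrackSet
#'
#' @param tracks a [TrackSet-class].
#' @param id track identity.
#' @return Data frame \code{frame, x, y, w, h}.
#' @export
trackBoxes <- function(tracks, id) {
  a <- assignments(tracks)
  a[a$id == id, c("frame", "x", "y", "w", "h"), drop = FALSE]
}
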