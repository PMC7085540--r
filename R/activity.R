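# Per-frame activity scoring of tracked boxes. Three interchangeable
# measures: maximum optical-flow magnitude in the box ("of"), interest
# point density ("stip"), and a pluggable per-box classifier confidence
# ("classifier").

#' Classifier activity of a box
#'
#' Delegates to a per-box scorer returning the active-class confidence in
#' \[0, 1\]; an optional threshold additionally flags the box as
#' active/inactive.
#'
#' @param box a box (see [boxCentroid()]).
#' @param scorer function \code{f(frame, box)} returning a confidence in
#'   \[0, 1\] (see [oracleScorer()] for a ground-truth-backed example).
#' @param frame 0-based frame index passed through to the scorer.
#' @param threshold optional active/inactive flagging threshold.
#' @return List with \code{value} (the confidence) and \code{active}
#'   (logical, NA when no threshold is given).
#' @export
activityClassifier <- function(box, scorer, frame = NA_integer_,
                               threshold = NULL) {
  value <- scorer(frame, box)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1)
    stop("scorer must return a single confidence in [0, 1]")
  list(value = value,
       active = if (is.null(threshold)) NA else value >= threshold)
}

#' Score every tracked box of one frame
#'
#' Produces one activity record per tracked box present in the frame, using
#' the requested measure.
#'
#' @param boxes data frame of this frame's tracked boxes (columns
#'   \code{frame, id, x, y, w, h}; ids must already be assigned by
#'   tracking).
#' @param measure \code{"of"}, \code{"stip"} or \code{"classifier"}.
#' @param flow a \code{FlowField} (required for \code{"of"}).
#' @param stips data frame from [harris3d()] (required for \code{"stip"}).
#' @param scorer per-box scorer (required for \code{"classifier"}).
#' @return Data frame \code{frame, track_id, measure, value} with one row
#'   per box.
#' @export
scoreFrame <- function(boxes, measure = c("of", "stip", "classifier"),
                       flow = NULL, stips = NULL, scorer = NULL) {
  measure <- match.arg(measure)
  if (nrow(boxes) == 0L)
    return(data.frame(frame = integer(), track_id = integer(),
                      measure = character(), value = numeric()))
  if (length(unique(boxes$frame)) != 1L)
    stop("scoreFrame expects boxes from a single frame")
  if (measure == "of" && is.null(flow))
    stop("measure 'of' needs a flow field for this frame")
  if (measure == "stip" && is.null(stips))
    stop("measure 'stip' needs the interest points")
  if (measure == "classifier" && is.null(scorer))
    stop("measure 'classifier' needs a scorer")
  f <- boxes$frame[1]
  vals <- vapply(seq_len(nrow(boxes)), function(i) {
    b <- asBoxMatrix(boxes[i, , drop = FALSE])
    switch(measure,
           of = activityOF(b, flow),
           stip = activitySTIP(b, stips, frame = f),
           classifier = activityClassifier(b, scorer, frame = f)$value)
  }, numeric(1))
  data.frame(frame = f, track_id = as.integer(boxes$id), measure = measure,
             value = vals)
}

#' Compute the activity table of a tracked sequence
#'
#' Scores every (frame, track) assignment of a [TrackSet-class] with the
#' configured measure. For the optical-flow measure the flow of frame t is
#' estimated between frames t and t+1; the final frame reuses the preceding
#' field so every frame gets a value. For the interest-point measure the
#' detector runs once over the whole volume.
#'
#' @param tracks a [TrackSet-class].
#' @param cfg a [PipelineConfig-class]; \code{cfg@measure} picks the
#'   measure and the flow/STIP parameters come from its slots.
#' @param frames list of intensity matrices (required for \code{"of"} and,
#'   unless \code{stips} is supplied, for \code{"stip"}).
#' @param stips precomputed [harris3d()] output (optional).
#' @param scorer per-box scorer for \code{"classifier"}.
#' @return Data frame \code{frame, track_id, measure, value}.
#' @export
computeActivity <- function(tracks, cfg = pipelineConfig(), frames = NULL,
                            stips = NULL, scorer = NULL) {
  stopifnot(is(tracks, "TrackSet"))
  a <- tracks@assignments
  if (nrow(a) == 0L)
    return(data.frame(frame = integer(), track_id = integer(),
                      measure = character(), value = numeric()))
  measure <- cfg@measure
  if (measure == "of" && is.null(frames))
    stop("measure 'of' needs the frame sequence")
  if (measure == "stip" && is.null(stips)) {
    if (is.null(frames)) stop("measure 'stip' needs frames or interest points")
    stips <- harris3d(frames, sigma2 = cfg@stipSigma2, tau2 = cfg@stipTau2,
                      s = cfg@stipS, k = cfg@stipK,
                      threshold = cfg@stipThreshold)
  }
  frameIdx <- sort(unique(a$frame))
  out <- vector("list", length(frameIdx))
  lastFlow <- NULL
  for (i in seq_along(frameIdx)) {
    f <- frameIdx[i]
    flow <- NULL
    if (measure == "of") {
      if (f + 2L <= length(frames)) {
        flow <- lucasKanadeFlow(frames[[f + 1L]], frames[[f + 2L]],
                                block = cfg@flowBlock,
                                window = cfg@flowWindow,
                                maxIter = cfg@flowIterations)
      } else if (!is.null(lastFlow)) {
        flow <- lastFlow                 # final frame: reuse (t-1, t) field
      } else if (f >= 1L) {
        flow <- lucasKanadeFlow(frames[[f]], frames[[f + 1L]],
                                block = cfg@flowBlock,
                                window = cfg@flowWindow,
                                maxIter = cfg@flowIterations)
      } else {
        stop("optical flow needs at least two frames")
      }
      lastFlow <- flow
    }
    out[[i]] <- scoreFrame(a[a$frame == f, , drop = FALSE], measure,
                           flow = flow, stips = stips, scorer = scorer)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
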