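# S4 containers exchanged between the pipeline stages.

detectionCols <- c("frame", "id", "x", "y", "w", "h", "conf", "label")

emptyDetectionFrame <- function(active = FALSE) {
  d <- data.frame(frame = integer(), id = integer(), x = numeric(),
                  y = numeric(), w = numeric(), h = numeric(),
                  conf = numeric(), label = character(),
                  stringsAsFactors = FALSE)
  if (active) d$active <- integer()
  d
}

#' DetectionSet: per-frame bounding-box detections
#'
#' Wraps a data frame of detections with columns \code{frame} (0-based
#' integer index), \code{id} (track identity, -1 for raw detections),
#' \code{x, y, w, h} (box, pixels), \code{conf} (score in \[0, 1\]) and
#' \code{label} (class name). Ground-truth sets may carry an extra
#' \code{active} column (0/1) flagging the active subject's box.
#'
#' @slot detections the detection data frame, sorted by frame.
#' @export
setClass("DetectionSet", representation(detections = "data.frame"))

setValidity("DetectionSet", function(object) {
  d <- object@detections
  if (!all(detectionCols %in% names(d)))
    return(paste("missing columns:",
                 paste(setdiff(detectionCols, names(d)), collapse = ", ")))
  if (nrow(d) == 0L) return(TRUE)
  if (any(d$frame < 0)) return("frame indices must be >= 0")
  if (any(d$w <= 0) || any(d$h <= 0)) return("box width and height must be > 0")
  if (any(d$conf < 0 | d$conf > 1)) return("confidence must lie in [0, 1]")
  if (is.unsorted(d$frame)) return("detections must be sorted by frame")
  TRUE
})

#' Construct a DetectionSet
#'
#' @param detections data frame with (at least) columns
#'   \code{frame, x, y, w, h}; missing \code{id}, \code{conf}, \code{label}
#'   columns are filled with -1, 1 and \code{"person"}.
#' @return A [DetectionSet-class] object.
#' @export
DetectionSet <- function(detections = emptyDetectionFrame()) {
  d <- as.data.frame(detections)
  if (nrow(d) > 0L) {
    if (is.null(d$id)) d$id <- -1L
    if (is.null(d$conf)) d$conf <- 1
    if (is.null(d$label)) d$label <- "person"
    d$frame <- as.integer(d$frame)
    d$id <- as.integer(d$id)
    d <- d[order(d$frame), , drop = FALSE]
    rownames(d) <- NULL
  } else {
    d <- emptyDetectionFrame(active = "active" %in% names(d))
  }
  keep <- c(detectionCols, intersect("active", names(d)))
  new("DetectionSet", detections = d[, keep, drop = FALSE])
}

#' TrackSet: identity-resolved box assignments
#'
#' The tracker output: one row per (frame, box) assignment with the track
#' \code{id} filled in, plus per-track summary info (first/last frame,
#' length, whether the track was closed by the miss limit).
#'
#' @slot assignments data frame \code{frame, id, x, y, w, h}.
#' @slot info data frame \code{id, start, end, n, closed}.
#' @export
setClass("TrackSet",
         representation(assignments = "data.frame", info = "data.frame"))

setValidity("TrackSet", function(object) {
  a <- object@assignments
  need <- c("frame", "id", "x", "y", "w", "h")
  if (!all(need %in% names(a)))
    return("assignments need columns frame, id, x, y, w, h")
  if (nrow(a) > 0L) {
    bad <- vapply(split(a$frame, a$id),
                  function(f) is.unsorted(f, strictly = TRUE), logical(1))
    if (any(bad))
      return("frame indices must be strictly increasing within each track")
    if (any(a$w <= 0) || any(a$h <= 0))
      return("box width and height must be > 0")
  }
  TRUE
})

TrackSet <- function(assignments, info = NULL) {
  a <- as.data.frame(assignments)
  if (nrow(a) > 0L) {
    a$frame <- as.integer(a$frame)
    a$id <- as.integer(a$id)
    a <- a[order(a$id, a$frame), c("frame", "id", "x", "y", "w", "h")]
    rownames(a) <- NULL
  } else {
    a <- data.frame(frame = integer(), id = integer(), x = numeric(),
                    y = numeric(), w = numeric(), h = numeric())
  }
  if (is.null(info)) {
    if (nrow(a) > 0L) {
      sp <- split(a$frame, a$id)
      info <- data.frame(id = as.integer(names(sp)),
                         start = vapply(sp, min, integer(1)),
                         end = vapply(sp, max, integer(1)),
                         n = lengths(sp), closed = FALSE,
                         row.names = NULL)
      info <- info[order(info$id), ]
    } else {
      info <- data.frame(id = integer(), start = integer(), end = integer(),
                         n = integer(), closed = logical())
    }
  }
  new("TrackSet", assignments = a, info = info)
}

#' SceneTruth: ground truth of a synthetic scene
#'
#' @slot boxes data frame \code{frame, id, x, y, w, h} with one box per live
#'   sprite per frame.
#' @slot activeId identity of the designated active sprite.
#' @slot frameSize integer (width, height) in pixels.
#' @slot nFrames number of frames.
#' @export
setClass("SceneTruth",
         representation(boxes = "data.frame", activeId = "integer",
                        frameSize = "integer", nFrames = "integer"))

setValidity("SceneTruth", function(object) {
  b <- object@boxes
  if (!all(c("frame", "id", "x", "y", "w", "h") %in% names(b)))
    return("boxes need columns frame, id, x, y, w, h")
  if (length(object@activeId) != 1L) return("exactly one active sprite")
  if (nrow(b) > 0L) {
    if (any(b$x < 0 | b$y < 0 |
            b$x + b$w > object@frameSize[1] |
            b$y + b$h > object@frameSize[2]))
      return("ground-truth boxes must lie inside the frame")
    if (anyDuplicated(b[, c("frame", "id")]))
      return("one box per sprite per frame")
  }
  TRUE
})

#' SelectionResult: the active-track decision for a sequence
#'
#' @slot activeId selected track id (NA when no track ever wins a frame).
#' @slot wins named integer vector: rank-1 frame counts per track.
#' @slot ranks data frame \code{frame, id, rank} (the track score vectors in
#'   long form; frames where a track is undetected are simply absent).
#' @slot frameActive data frame \code{frame, active}: per-frame active track
#'   id, NA where the top activity value was tied.
#' @export
setClass("SelectionResult",
         representation(activeId = "integer", wins = "integer",
                        ranks = "data.frame", frameActive = "data.frame"))

setValidity("SelectionResult", function(object) {
  if (length(object@activeId) != 1L) return("activeId must have length 1")
  if (length(object@wins) > 0L && !is.na(object@activeId) &&
      object@wins[as.character(object@activeId)] != max(object@wins))
    return("the selected track must have maximal wins")
  TRUE
})

#' EvalReport: detection / activity evaluation counts and scores
#'
#' @slot tp,fp,fn true positive, false positive and false negative counts.
#' @slot precision,recall,f1 the derived ratios (0 with a note when a
#'   denominator is empty).
#' @slot note diagnostic flags, e.g. \code{"no-predictions"}.
#' @export
setClass("EvalReport",
         representation(tp = "integer", fp = "integer", fn = "integer",
                        precision = "numeric", recall = "numeric",
                        f1 = "numeric", note = "character"))

EvalReport <- function(tp, fp, fn, note = character()) {
  tp <- as.integer(tp); fp <- as.integer(fp); fn <- as.integer(fn)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else {
    note <- union(note, "no-predictions"); 0
  }
  recall <- if (tp + fn > 0L) tp / (tp + fn) else {
    note <- union(note, "no-ground-truth"); 0
  }
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  new("EvalReport", tp = tp, fp = fp, fn = fn, precision = precision,
      recall = recall, f1 = f1, note = note)
}

#' PipelineRun: the full result of one orchestrated pipeline run
#'
#' @slot tracks the [TrackSet-class] produced by the tracking stage.
#' @slot selection the [SelectionResult-class].
#' @slot activity the per-frame activity table
#'   (\code{frame, track_id, measure, value, rank, is_active}).
#' @slot trajectory centroid polyline of the selected track
#'   (\code{frame, cx, cy}).
#' @slot crops thumbnail index of the selected track
#'   (\code{frame, x, y, w, h}).
#' @slot manifest reproducibility record: config snapshot, seed, input
#'   hashes, stage counts, package version.
#' @export
setClass("PipelineRun",
         representation(tracks = "TrackSet", selection = "SelectionResult",
                        activity = "data.frame", trajectory = "data.frame",
                        crops = "data.frame", manifest = "list"))
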