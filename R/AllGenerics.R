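# Accessor generics and show methods.

#' Accessors for ActiveTracker containers
#'
#' \code{detections()} returns the detection data frame of a
#' [DetectionSet-class]; \code{assignments()} and \code{trackInfo()} the
#' tables of a [TrackSet-class]; \code{trackIds()} the identities present;
#' \code{truthBoxes()} and \code{activeId()} the ground truth of a
#' [SceneTruth-class]; \code{activeTrack()} and \code{wins()} the decision of
#' a [SelectionResult-class] (or [PipelineRun-class]).
#'
#' @param x the container.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("trackInfo", function(x) standardGeneric("trackInfo"))
#' @rdname accessors
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))
#' @rdname accessors
#' @export
setGeneric("truthBoxes", function(x) standardGeneric("truthBoxes"))
#' @rdname accessors
#' @export
setGeneric("activeId", function(x) standardGeneric("activeId"))
#' @rdname accessors
#' @export
setGeneric("activeTrack", function(x) standardGeneric("activeTrack"))
#' @rdname accessors
#' @export
setGeneric("wins", function(x) standardGeneric("wins"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setMethod("detections", "DetectionSet", function(x) x@detections)
#' @rdname accessors
#' @export
setMethod("nFrames", "DetectionSet", function(x) {
  if (nrow(x@detections) == 0L) 0L else max(x@detections$frame) + 1L
})
#' @rdname accessors
#' @export
setMethod("assignments", "TrackSet", function(x) x@assignments)
#' @rdname accessors
#' @export
setMethod("trackInfo", "TrackSet", function(x) x@info)
#' @rdname accessors
#' @export
setMethod("trackIds", "TrackSet", function(x) sort(unique(x@assignments$id)))
#' @rdname accessors
#' @export
setMethod("truthBoxes", "SceneTruth", function(x) x@boxes)
#' @rdname accessors
#' @export
setMethod("activeId", "SceneTruth", function(x) x@activeId)
#' @rdname accessors
#' @export
setMethod("nFrames", "SceneTruth", function(x) x@nFrames)
#' @rdname accessors
#' @export
setMethod("activeTrack", "SelectionResult", function(x) x@activeId)
#' @rdname accessors
#' @export
setMethod("wins", "SelectionResult", function(x) x@wins)
#' @rdname accessors
#' @export
setMethod("activeTrack", "PipelineRun", function(x) x@selection@activeId)
#' @rdname accessors
#' @export
setMethod("wins", "PipelineRun", function(x) x@selection@wins)

setMethod("show", "DetectionSet", function(object) {
  d <- object@detections
  cat(sprintf("DetectionSet: %d detections over %d frame(s)\n",
              nrow(d), length(unique(d$frame))))
  if (nrow(d) > 0L)
    cat(sprintf("  frames %d..%d, confidence %.2f..%.2f, labels: %s\n",
                min(d$frame), max(d$frame), min(d$conf), max(d$conf),
                paste(unique(d$label), collapse = ", ")))
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d track(s), %d assignment(s)\n",
              nrow(object@info), nrow(object@assignments)))
  if (nrow(object@info) > 0L) {
    cat(sprintf("  lengths %d..%d frames, %d closed\n",
                min(object@info$n), max(object@info$n),
                sum(object@info$closed)))
  }
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: %d sprite(s), %d frames, %dx%d px, active id %d\n",
              length(unique(object@boxes$id)), object@nFrames,
              object@frameSize[1], object@frameSize[2], object@activeId))
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult\n")
  if (is.na(object@activeId)) {
    cat("  no active track (no frame had a unique top activity)\n")
  } else {
    cat(sprintf("  active track: %d (%d win(s) over %d ranked frame(s))\n",
                object@activeId, object@wins[as.character(object@activeId)],
                length(unique(object@ranks$frame))))
  }
  if (length(object@wins) > 0L) {
    cat("  wins: ",
        paste(sprintf("%s=%d", names(object@wins), object@wins),
              collapse = " "), "\n")
  }
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: TP=%d FP=%d FN=%d | P=%.3f R=%.3f F1=%.3f\n",
              object@tp, object@fp, object@fn, object@precision,
              object@recall, object@f1))
  if (length(object@note) > 0L)
    cat("  note:", paste(object@note, collapse = "; "), "\n")
})

setMethod("show", "PipelineRun", function(object) {
  cat("PipelineRun\n")
  cat(sprintf("  tracks: %d | activity records: %d | measure: %s | tracker: %s\n",
              nrow(object@tracks@info), nrow(object@activity),
              object@manifest$config$measure, object@manifest$config$tracker))
  show(object@selection)
})
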