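# Orchestration: filter -> track -> score -> rank -> select, with a
# reproducibility manifest. Every stage's output is plain data and can be
# serialised/reloaded independently through the formats in io.R.

#' Filter raw detections by confidence and class label
#'
#' Keeps detections whose label matches and whose confidence is at least
#' the threshold (the boundary value is kept).
#'
#' @param dets a [DetectionSet-class].
#' @param threshold minimum confidence in \[0, 1\] (default 0.55).
#' @param label class label to keep (default "person"; NULL keeps every
#'   label).
#' @return The filtered [DetectionSet-class].
#' @export
filterDetections <- function(dets, threshold = 0.55, label = "person") {
  stopifnot(is(dets, "DetectionSet"), threshold >= 0, threshold <= 1)
  d <- dets@detections
  keep <- d$conf >= threshold
  if (!is.null(label)) keep <- keep & d$label == label
  atLog(sprintf("filter: kept %d of %d detections (conf >= %.2f)",
                sum(keep), nrow(d), threshold))
  DetectionSet(d[keep, , drop = FALSE])
}

#' Run the full active-subject pipeline
#'
#' Executes every stage in order: confidence/label filtering, tracking
#' (Hungarian or Deep-SORT-style), per-frame activity scoring, per-frame
#' ranking, and active-track selection. The result bundles the tracks, the
#' augmented activity table, the selection, the selected track's centroid
#' trajectory and thumbnail-crop index, and a manifest (config snapshot,
#' seed, input hashes, per-stage counts, package version) under which
#' deterministic stages reproduce bitwise.
#'
#' @param frames list of intensity matrices ([loadFrames()] /
#'   [generateScene()]).
#' @param dets raw detections ([DetectionSet-class]).
#' @param cfg a [PipelineConfig-class].
#' @param scorer per-box scorer, required when \code{cfg@measure} is
#'   \code{"classifier"}.
#' @param embedder appearance embedder for the Deep-SORT-style tracker.
#' @return A [PipelineRun-class].
#' @export
runPipeline <- function(frames, dets, cfg = pipelineConfig(),
                        scorer = NULL, embedder = defaultEmbedder) {
  stopifnot(is(dets, "DetectionSet"), is(cfg, "PipelineConfig"))
  stage <- "filter"
  result <- tryCatch({
    filtered <- filterDetections(dets, cfg@detectionConfThreshold,
                                 cfg@detectionLabel)
    stage <- "track"
    tracks <- trackDetections(filtered, cfg, frames = frames,
                              embedder = embedder)
    stage <- "activity"
    activity <- computeActivity(tracks, cfg, frames = frames,
                                scorer = scorer)
    stage <- "select"
    ranked <- rankActivity(activity)
    selection <- selectActive(ranked$scoreVectors)
    list(filtered = filtered, tracks = tracks,
         activity = ranked$activity, selection = selection)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  sel <- result$selection
  if (!is.na(sel@activeId)) {
    tb <- trackBoxes(result$tracks, sel@activeId)
    trajectory <- data.frame(frame = tb$frame,
                             cx = tb$x + tb$w / 2, cy = tb$y + tb$h / 2)
    crops <- tb
  } else {
    trajectory <- data.frame(frame = integer(), cx = numeric(),
                             cy = numeric())
    crops <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                        w = numeric(), h = numeric())
  }
  manifest <- list(
    config = configAsList(cfg),
    seed = cfg@seed,
    nFrames = length(frames),
    frameSize = if (length(frames) > 0L)
      c(ncol(frames[[1]]), nrow(frames[[1]])) else c(NA, NA),
    inputHashes = list(detections = objectHash(dets@detections),
                       frames = objectHash(frames)),
    counts = list(rawDetections = nrow(dets@detections),
                  keptDetections = nrow(result$filtered@detections),
                  tracks = nrow(result$tracks@info),
                  activityRecords = nrow(result$activity)),
    version = as.character(utils::packageVersion("ActiveTracker")))
  new("PipelineRun", tracks = result$tracks, selection = sel,
      activity = result$activity, trajectory = trajectory, crops = crops,
      manifest = manifest)
}
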