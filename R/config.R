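# Pipeline configuration. Defaults follow the method's published operating
# point where one is printed (confidence threshold 0.55, T = 100 px,
# M = 20 frames, descriptor gallery of 100, 128-element descriptors,
# Harris corner parameter k = 0.005, minimum activity IoU 10%, track
# evaluation alpha = theta = 50%); the remaining knobs are documented
# package choices.

#' PipelineConfig: every tunable parameter of the pipeline
#'
#' @slot detectionConfThreshold minimum detection confidence kept by
#'   [filterDetections()] (default 0.55; the boundary value is kept).
#' @slot detectionLabel class label kept by the filter (default "person").
#' @slot tracker \code{"hungarian"} or \code{"deepsort"}.
#' @slot w weight in \[0, 1\] blending centroid distance (px) against
#'   absolute area difference (px^2) in the Hungarian cost (default 0.5).
#' @slot T centroid-distance gate in pixels: a detection farther than T from
#'   a track's last box cannot join it (default 100).
#' @slot M maximum number of consecutive unassigned frames before a track is
#'   closed (default 20).
#' @slot lambda weight in \[0, 1\] blending Mahalanobis against appearance
#'   distance in the Deep-SORT-style cost (default 0.5).
#' @slot gallerySize appearance gallery capacity per track (default 100).
#' @slot descriptorDim appearance descriptor length (default 128).
#' @slot gateMahalanobis maximum admissible squared Mahalanobis distance
#'   (default 9.4877, the chi-square 0.95 quantile with 4 dof).
#' @slot gateAppearance maximum admissible cosine appearance distance
#'   (default 0.2).
#' @slot measure activity measure: \code{"of"} (optical flow),
#'   \code{"stip"} (interest-point density) or \code{"classifier"}.
#' @slot flowBlock,flowWindow,flowIterations Lucas-Kanade section size,
#'   aggregation window (px) and refinement iteration cap (8, 16, 5).
#' @slot stipSigma2,stipTau2 spatial and temporal variances of the Harris3D
#'   smoothing kernel (4, 2).
#' @slot stipS integration-scale factor (2).
#' @slot stipK corner-function parameter (0.005).
#' @slot stipThreshold minimum corner response for a reported interest point
#'   (1e-13 on unit-range intensities, calibrated on synthetic scenes).
#' @slot classifierThreshold active/inactive flagging threshold for the
#'   classifier measure (0.5).
#' @slot alpha per-frame IoU threshold of the track-level metric (0.5).
#' @slot theta minimum fraction of matching frames of the track-level
#'   metric (0.5).
#' @slot minActivityIoU minimum IoU for a frame-level activity true positive
#'   (0.1).
#' @slot detectionIoU IoU threshold for a detection true positive (0.5).
#' @slot seed integer seed governing every stochastic stage.
#' @export
setClass("PipelineConfig", representation(
  detectionConfThreshold = "numeric", detectionLabel = "character",
  tracker = "character", w = "numeric", T = "numeric", M = "integer",
  lambda = "numeric", gallerySize = "integer", descriptorDim = "integer",
  gateMahalanobis = "numeric", gateAppearance = "numeric",
  measure = "character", flowBlock = "integer", flowWindow = "integer",
  flowIterations = "integer", stipSigma2 = "numeric", stipTau2 = "numeric",
  stipS = "numeric", stipK = "numeric", stipThreshold = "numeric",
  classifierThreshold = "numeric", alpha = "numeric", theta = "numeric",
  minActivityIoU = "numeric", detectionIoU = "numeric", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  ratio <- c(detectionConfThreshold = object@detectionConfThreshold,
             w = object@w, lambda = object@lambda, alpha = object@alpha,
             theta = object@theta, minActivityIoU = object@minActivityIoU,
             detectionIoU = object@detectionIoU,
             classifierThreshold = object@classifierThreshold)
  if (any(ratio < 0 | ratio > 1))
    return(paste("must lie in [0, 1]:",
                 paste(names(ratio)[ratio < 0 | ratio > 1], collapse = ", ")))
  if (object@T <= 0 || object@M <= 0 || object@gallerySize <= 0 ||
      object@descriptorDim <= 0)
    return("T, M, gallerySize and descriptorDim must be positive")
  if (!object@tracker %in% c("hungarian", "deepsort"))
    return("tracker must be 'hungarian' or 'deepsort'")
  if (!object@measure %in% c("of", "stip", "classifier"))
    return("measure must be 'of', 'stip' or 'classifier'")
  if (any(c(object@stipSigma2, object@stipTau2, object@stipS, object@stipK,
            object@stipThreshold) <= 0))
    return("STIP parameters must be positive")
  TRUE
})

#' Construct a pipeline configuration
#'
#' All arguments default to the documented operating point; see
#' [PipelineConfig-class] for the meaning and default of each slot.
#'
#' @param ... named slot values overriding the defaults.
#' @return A validated [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig(tracker = "deepsort", measure = "stip")
#' cfg@T
#' @export
pipelineConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    detectionConfThreshold = 0.55, detectionLabel = "person",
    tracker = "hungarian", w = 0.5, T = 100, M = 20L, lambda = 0.5,
    gallerySize = 100L, descriptorDim = 128L, gateMahalanobis = 9.4877,
    gateAppearance = 0.2, measure = "of", flowBlock = 8L, flowWindow = 16L,
    flowIterations = 5L, stipSigma2 = 4, stipTau2 = 2, stipS = 2,
    stipK = 0.005, stipThreshold = 1e-13, classifierThreshold = 0.5,
    alpha = 0.5, theta = 0.5, minActivityIoU = 0.1, detectionIoU = 0.5,
    seed = 1L)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown configuration parameter(s): ",
         paste(unknown, collapse = ", "))
  vals <- utils::modifyList(defaults, args)
  for (nm in c("M", "gallerySize", "descriptorDim", "flowBlock",
               "flowWindow", "flowIterations", "seed"))
    vals[[nm]] <- as.integer(vals[[nm]])
  do.call(new, c(list("PipelineConfig"), vals))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  detection: conf >= %.2f, label '%s'\n",
              object@detectionConfThreshold, object@detectionLabel))
  cat(sprintf("  tracker: %s (w=%.2f T=%g M=%d | lambda=%.2f gallery=%d dim=%d)\n",
              object@tracker, object@w, object@T, object@M, object@lambda,
              object@gallerySize, object@descriptorDim))
  cat(sprintf("  measure: %s | flow %dpx/%dpx | stip s2=%g t2=%g k=%g\n",
              object@measure, object@flowBlock, object@flowWindow,
              object@stipSigma2, object@stipTau2, object@stipK))
  cat(sprintf("  eval: alpha=%.2f theta=%.2f minActivityIoU=%.2f | seed=%d\n",
              object@alpha, object@theta, object@minActivityIoU, object@seed))
})

configAsList <- function(cfg) {
  nms <- slotNames("PipelineConfig")
  stats::setNames(lapply(nms, function(s) slot(cfg, s)), nms)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path of a YAML key-value file; keys are the slot names
#'   of [PipelineConfig-class], all optional.
#' @return \code{readConfig()} returns a [PipelineConfig-class];
#'   \code{writeConfig()} invisibly returns \code{path}.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipelineConfig, vals)
}

#' @rdname readConfig
#' @param cfg a [PipelineConfig-class] object.
#' @export
writeConfig <- function(cfg, path) {
  stopifnot(is(cfg, "PipelineConfig"))
  yaml::write_yaml(configAsList(cfg), path)
  invisible(path)
}
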