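# Tracking-by-detection. Two interchangeable assignment costs drive the
# same online track-management loop:
#   * "hungarian": w * centroid distance + (1 - w) * |area difference|,
#     gated at centroid distance T;
#   * "deepsort": lambda * squared Mahalanobis distance from a
#     constant-velocity Kalman prediction + (1 - lambda) * cosine
#     appearance distance to a bounded descriptor gallery, each term gated
#     separately.
# Matched tracks are extended; unmatched tracks accumulate misses and are
# closed after more than M consecutive unassigned frames; every unmatched
# detection spawns a new track with a fresh id.

#' Hungarian tracking cost between a track and a detection
#'
#' \code{w * d(C_last, C_det) + (1 - w) * |P_det - P_last|}, where d is the
#' Euclidean centroid distance in pixels and P the box areas in square
#' pixels, combined raw as printed. Returns \code{Inf} (infeasible) when
#' the centroid distance is >= the gate \code{T}.
#'
#' @param track internal track record (list with a \code{boxes} matrix) or
#'   anything accepted by [boxCentroid()] giving the track's last box.
#' @param det the candidate detection box.
#' @param w blend weight in \[0, 1\].
#' @param T centroid-distance gate in pixels.
#' @return Non-negative cost, or \code{Inf} when gated.
#' @examples
#' a <- bbox(5, 5, 10, 10)      # centred (10, 10), area 100
#' b <- bbox(7.5, 9, 11, 10)    # centred (13, 14), area 110
#' hungarianCost(a, b, w = 0.5) # 0.5 * 5 + 0.5 * 10 = 7.5
#' @export
hungarianCost <- function(track, det, w = 0.5, T = 100) {
  last <- trackLastBox(track)
  d <- centroidDistance(last, det)
  if (d >= T) return(Inf)
  w * d + (1 - w) * abs(boxArea(det) - boxArea(last))
}

trackLastBox <- function(track) {
  if (is.list(track) && !is.data.frame(track) && !is.null(track$boxes)) {
    if (nrow(track$boxes) == 0L) stop("track has no assignments")
    return(track$boxes[nrow(track$boxes), , drop = FALSE])
  }
  asBoxMatrix(track)
}

#' Deep-SORT-style blended cost from component distances
#'
#' \code{lambda * d1 + (1 - lambda) * d2} where \code{d1} is the squared
#' Mahalanobis distance ([mahalanobisDistance()]) and \code{d2} the cosine
#' appearance distance ([appearanceDistance()]). The pair is infeasible
#' (\code{Inf}) when either distance exceeds its gate.
#'
#' @param d1 squared Mahalanobis distance.
#' @param d2 cosine appearance distance.
#' @param lambda blend weight in \[0, 1\].
#' @param gateMahalanobis maximum admissible \code{d1} (default 9.4877, the
#'   chi-square 0.95 quantile at 4 dof).
#' @param gateAppearance maximum admissible \code{d2} (default 0.2).
#' @return The blended cost, or \code{Inf} when gated.
#' @export
deepsortCost <- function(d1, d2, lambda = 0.5, gateMahalanobis = 9.4877,
                         gateAppearance = 0.2) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (d1 > gateMahalanobis || d2 > gateAppearance) return(Inf)
  lambda * d1 + (1 - lambda) * d2
}

# Build the (tracks x detections) cost matrix for one frame.
trackerCostMatrix <- function(tracks, detBoxes, cfg, descriptors = NULL) {
  nT <- length(tracks)
  nD <- nrow(detBoxes)
  cost <- matrix(Inf, nT, nD)
  if (nT == 0L || nD == 0L) return(cost)
  for (i in seq_len(nT)) {
    tr <- tracks[[i]]
    if (cfg@tracker == "hungarian") {
      for (j in seq_len(nD))
        cost[i, j] <- hungarianCost(tr, detBoxes[j, , drop = FALSE],
                                    w = cfg@w, T = cfg@T)
    } else {
      proj <- kfProject(tr$kf)
      for (j in seq_len(nD)) {
        d1 <- mahalanobisDistance(proj$mean, proj$cov,
                                  boxToMeasurement(detBoxes[j, , drop = FALSE]))
        d2 <- appearanceDistance(tr$gallery, descriptors[[j]])
        cost[i, j] <- deepsortCost(d1, d2, lambda = cfg@lambda,
                                   gateMahalanobis = cfg@gateMahalanobis,
                                   gateAppearance = cfg@gateAppearance)
      }
    }
  }
  cost
}

#' Assign one frame of detections to open tracks
#'
#' Builds the pairwise cost matrix ([hungarianCost()] or the
#' Deep-SORT-style blend) and solves the global minimum-total-cost
#' one-to-one assignment over the feasible pairs ([solveAssignment()]).
#' Leftover tracks and detections are reported unmatched.
#'
#' @param tracks list of open internal track records (see [newTracker()]).
#' @param dets data frame of this frame's detections (columns
#'   \code{x, y, w, h}).
#' @param cfg a [PipelineConfig-class].
#' @param descriptors list of appearance descriptors per detection
#'   (required for the \code{"deepsort"} tracker).
#' @return List with \code{matches} (columns \code{track}, \code{detection};
#'   indices into the inputs), \code{unmatchedTracks},
#'   \code{unmatchedDetections}.
#' @export
assignHungarian <- function(tracks, dets, cfg = pipelineConfig(),
                            descriptors = NULL) {
  detBoxes <- if (nrow(dets) > 0L) asBoxMatrix(dets) else
    matrix(numeric(), 0L, 4L, dimnames = list(NULL, c("x", "y", "w", "h")))
  cost <- trackerCostMatrix(tracks, detBoxes, cfg, descriptors)
  sol <- solveAssignment(cost)
  list(matches = matrix(sol$matches, ncol = 2L,
                        dimnames = list(NULL, c("track", "detection"))),
       unmatchedTracks = sol$unmatchedRows,
       unmatchedDetections = sol$unmatchedCols)
}

#' Create an empty tracker state
#'
#' The state is a plain list: \code{tracks} (every track record, open or
#' closed), \code{nextId}, and \code{lastFrame}. Each track record holds
#' \code{id}, \code{frames}, \code{boxes} (n x 4 matrix), \code{misses},
#' \code{closed}, and for the Deep-SORT backend a Kalman state \code{kf}
#' and descriptor \code{gallery}.
#'
#' @return The initial state.
#' @export
newTracker <- function() {
  list(tracks = list(), nextId = 1L, lastFrame = -1L)
}

#' Advance the tracker by one frame
#'
#' Matches the frame's detections to the open tracks, extends matched
#' tracks (resetting their miss counters), increments the miss counter of
#' unmatched tracks and closes those exceeding \code{M} consecutive misses,
#' and spawns a new track for every unmatched detection. Frames must be
#' processed in strictly increasing order.
#'
#' @param state tracker state from [newTracker()] / a previous step.
#' @param frame 0-based frame index being processed.
#' @param dets data frame of detections in this frame (columns
#'   \code{x, y, w, h}; extra columns ignored).
#' @param cfg a [PipelineConfig-class].
#' @param image the frame's intensity matrix (required by the
#'   \code{"deepsort"} tracker for appearance descriptors).
#' @param embedder appearance embedder function \code{f(image, box)}.
#' @return The updated state.
#' @export
stepTracker <- function(state, frame, dets, cfg = pipelineConfig(),
                        image = NULL, embedder = defaultEmbedder) {
  frame <- as.integer(frame)
  if (frame <= state$lastFrame)
    stop(sprintf("frame %d is not after the last processed frame %d",
                 frame, state$lastFrame))
  deepsort <- cfg@tracker == "deepsort"
  open <- which(vapply(state$tracks, function(t) !t$closed, logical(1)))
  openTracks <- state$tracks[open]
  if (deepsort) {
    if (is.null(image) && nrow(dets) > 0L)
      stop("the deepsort tracker needs the frame image for appearance")
    # predict all open tracks forward to this frame (skipped frames too)
    reps <- max(1L, frame - state$lastFrame)
    for (k in seq_along(openTracks)) {
      tr <- openTracks[[k]]
      for (s in seq_len(reps)) tr$kf <- kfPredict(tr$kf)
      openTracks[[k]] <- tr
    }
  }
  descriptors <- NULL
  if (deepsort && nrow(dets) > 0L) {
    descriptors <- lapply(seq_len(nrow(dets)), function(j)
      embedder(image, asBoxMatrix(dets[j, , drop = FALSE])))
  }
  res <- assignHungarian(openTracks, dets, cfg, descriptors)
  detBoxes <- if (nrow(dets) > 0L) asBoxMatrix(dets) else NULL
  # extend matched tracks
  if (nrow(res$matches) > 0L) {
    for (r in seq_len(nrow(res$matches))) {
      k <- res$matches[r, 1L]
      j <- res$matches[r, 2L]
      tr <- openTracks[[k]]
      box <- detBoxes[j, , drop = FALSE]
      tr$frames <- c(tr$frames, frame)
      tr$boxes <- rbind(tr$boxes, box)
      tr$misses <- 0L
      if (deepsort) {
        tr$kf <- kfUpdate(tr$kf, boxToMeasurement(box))
        tr$gallery <- c(tr$gallery, list(descriptors[[j]]))
        if (length(tr$gallery) > cfg@gallerySize)
          tr$gallery <- tr$gallery[seq.int(length(tr$gallery) -
                                             cfg@gallerySize + 1L,
                                           length(tr$gallery))]
      }
      openTracks[[k]] <- tr
    }
  }
  # age unmatched tracks
  gap <- max(1L, frame - state$lastFrame)
  for (k in res$unmatchedTracks) {
    tr <- openTracks[[k]]
    tr$misses <- tr$misses + gap
    if (tr$misses > cfg@M) tr$closed <- TRUE
    openTracks[[k]] <- tr
  }
  state$tracks[open] <- openTracks
  # spawn new tracks from unmatched detections
  for (j in res$unmatchedDetections) {
    box <- detBoxes[j, , drop = FALSE]
    tr <- list(id = state$nextId, frames = frame, boxes = box,
               misses = 0L, closed = FALSE)
    if (deepsort) {
      tr$kf <- kfInit(boxToMeasurement(box))
      tr$gallery <- list(descriptors[[j]])
    }
    state$tracks[[length(state$tracks) + 1L]] <- tr
    state$nextId <- state$nextId + 1L
  }
  state$lastFrame <- frame
  state
}

#' Track a detection stream through a sequence
#'
#' Runs [stepTracker()] over every frame of the sequence (frames with no
#' detections still age the open tracks) and collects the result into a
#' [TrackSet-class]. Track ids are unique and never reused within a run.
#'
#' @param dets a [DetectionSet-class] (typically after
#'   [filterDetections()]).
#' @param cfg a [PipelineConfig-class]; \code{cfg@tracker} picks the
#'   backend.
#' @param frames list of intensity matrices (required for
#'   \code{"deepsort"}); also fixes the number of processed frames.
#' @param embedder appearance embedder for the \code{"deepsort"} backend.
#' @return A [TrackSet-class].
#' @export
trackDetections <- function(dets, cfg = pipelineConfig(), frames = NULL,
                            embedder = defaultEmbedder) {
  stopifnot(is(dets, "DetectionSet"))
  d <- dets@detections
  nF <- if (!is.null(frames)) length(frames)
        else if (nrow(d) > 0L) max(d$frame) + 1L else 0L
  state <- newTracker()
  for (f in seq_len(nF) - 1L) {
    df <- d[d$frame == f, , drop = FALSE]
    state <- stepTracker(state, f, df, cfg,
                         image = if (!is.null(frames)) frames[[f + 1L]],
                         embedder = embedder)
  }
  trackerToTrackSet(state)
}

trackerToTrackSet <- function(state) {
  if (length(state$tracks) == 0L)
    return(TrackSet(data.frame(frame = integer(), id = integer(),
                               x = numeric(), y = numeric(), w = numeric(),
                               h = numeric())))
  parts <- lapply(state$tracks, function(tr)
    data.frame(frame = tr$frames, id = tr$id, x = tr$boxes[, "x"],
               y = tr$boxes[, "y"], w = tr$boxes[, "w"], h = tr$boxes[, "h"]))
  info <- data.frame(
    id = vapply(state$tracks, `[[`, integer(1), "id"),
    start = vapply(state$tracks, function(t) min(t$frames), numeric(1)),
    end = vapply(state$tracks, function(t) max(t$frames), numeric(1)),
    n = vapply(state$tracks, function(t) length(t$frames), integer(1)),
    closed = vapply(state$tracks, `[[`, logical(1), "closed"))
  TrackSet(do.call(rbind, parts), info = info[order(info$id), ])
}
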