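# Rank aggregation: within each frame, tracked boxes are ranked by
# activity (competition ranking, rank 1 = most active); per-track rank
# sequences are the track score vectors; the track whose vector contains
# the most rank-1 entries ("wins") is the sequence's active track. When
# several tracks tie for the top activity of a frame they all receive rank
# 1 in their score vectors, but no track is flagged active in that frame.
# A win additionally requires nonzero activity: a frame in which no box
# exhibits any measured activity carries no ranking information and
# contributes no win to anyone.

#' Rank one frame's activity records
#'
#' @param records data frame with columns \code{track_id} (or \code{id})
#'   and \code{value}, one row per track present in the frame; an optional
#'   \code{frame} column must be constant.
#' @return A \code{FrameRanking}: list with \code{frame}, \code{ranks} (a
#'   named integer vector, names = track ids, competition ranking with
#'   rank 1 = highest activity), \code{winners} (the rank-1 track ids with
#'   nonzero activity), and \code{active} (the single winner, or NA when
#'   the top value is shared or zero).
#' @examples
#' rankFrame(data.frame(track_id = c(6, 1, 2), value = c(0.9, 0.5, 0.3)))
#' @export
rankFrame <- function(records) {
  ids <- records$track_id
  if (is.null(ids)) ids <- records$id
  if (is.null(ids)) stop("records need a track_id (or id) column")
  if (anyDuplicated(ids)) stop("duplicate track ids in one frame")
  f <- if (!is.null(records$frame)) {
    if (length(unique(records$frame)) > 1L)
      stop("records span multiple frames")
    as.integer(records$frame[1])
  } else NA_integer_
  v <- records$value
  r <- as.integer(rank(-v, ties.method = "min"))
  top <- which(r == 1L & v > 0)
  structure(list(frame = f,
                 ranks = stats::setNames(r, as.character(as.integer(ids))),
                 winners = as.integer(ids[top]),
                 active = if (length(top) == 1L) as.integer(ids[top])
                          else NA_integer_),
            class = "FrameRanking")
}

#' Accumulate frame rankings into track score vectors
#'
#' Collects the per-frame ranks of every track (frames where a track is
#' undetected contribute no entry) and counts each track's wins: the number
#' of frames in which it holds rank 1 with nonzero activity. Rank-1 ties
#' count as a win for every tied track, but leave the frame without an
#' active flag. Rankings built directly from printed rank vectors (no
#' \code{winners} field) count every rank-1 entry.
#'
#' @param rankings list of \code{FrameRanking} objects ([rankFrame()]) with
#'   strictly increasing frame indices.
#' @return List of class \code{ScoreVectors}: \code{ranks} (long data frame
#'   \code{frame, id, rank}), \code{wins} (named integer vector),
#'   \code{tracked} (frames-per-track counts), and \code{frameActive} (data
#'   frame \code{frame, active}).
#' @export
accumulateRankings <- function(rankings) {
  if (length(rankings) == 0L)
    return(structure(list(ranks = data.frame(frame = integer(),
                                             id = integer(),
                                             rank = integer()),
                          wins = stats::setNames(integer(), character()),
                          tracked = stats::setNames(integer(), character()),
                          frameActive = data.frame(frame = integer(),
                                                   active = integer())),
                     class = "ScoreVectors"))
  fr <- vapply(rankings, function(r) r$frame, integer(1))
  if (anyNA(fr)) fr <- seq_along(rankings) - 1L
  if (is.unsorted(fr, strictly = TRUE))
    stop("frame indices must be strictly increasing")
  long <- do.call(rbind, lapply(seq_along(rankings), function(i) {
    rk <- rankings[[i]]$ranks
    data.frame(frame = fr[i], id = as.integer(names(rk)),
               rank = as.integer(rk))
  }))
  ids <- sort(unique(long$id))
  winnerList <- lapply(rankings, function(r) {
    if (!is.null(r$winners)) as.integer(r$winners)
    else as.integer(names(r$ranks))[r$ranks == 1L]
  })
  allWinners <- unlist(winnerList)
  wins <- vapply(ids, function(i) sum(allWinners == i), integer(1))
  tracked <- vapply(ids, function(i) sum(long$id == i), integer(1))
  frameActive <- data.frame(
    frame = fr,
    active = vapply(rankings, function(r) r$active, integer(1)))
  structure(list(ranks = long,
                 wins = stats::setNames(wins, as.character(ids)),
                 tracked = stats::setNames(tracked, as.character(ids)),
                 frameActive = frameActive),
            class = "ScoreVectors")
}

#' Select the sequence's active track
#'
#' The active track is the one most often ranked first, i.e. with the most
#' wins. Ties are broken in favour of the track observed in more frames,
#' then of the lower id. When no track wins any frame the result carries an
#' NA active id.
#'
#' @param scoreVectors a \code{ScoreVectors} object
#'   ([accumulateRankings()]).
#' @return A [SelectionResult-class].
#' @export
selectActive <- function(scoreVectors) {
  stopifnot(inherits(scoreVectors, "ScoreVectors"))
  w <- scoreVectors$wins
  if (length(w) == 0L || max(w) == 0L) {
    return(new("SelectionResult", activeId = NA_integer_,
               wins = stats::setNames(as.integer(w), names(w)),
               ranks = scoreVectors$ranks,
               frameActive = scoreVectors$frameActive))
  }
  cand <- names(w)[w == max(w)]
  if (length(cand) > 1L) {
    tr <- scoreVectors$tracked[cand]
    cand <- cand[tr == max(tr)]
    cand <- as.character(min(as.integer(cand)))
  }
  new("SelectionResult", activeId = as.integer(cand[1]),
      wins = stats::setNames(as.integer(w), names(w)),
      ranks = scoreVectors$ranks,
      frameActive = scoreVectors$frameActive)
}

#' Rank a whole activity table
#'
#' Convenience wrapper: splits an activity table by frame, applies
#' [rankFrame()], and returns both the accumulated score vectors and the
#' activity table augmented with \code{rank} and \code{is_active} columns.
#'
#' @param activity data frame \code{frame, track_id, measure, value}
#'   ([computeActivity()]).
#' @return List with \code{scoreVectors} and the augmented \code{activity}
#'   table.
#' @export
rankActivity <- function(activity) {
  frameIdx <- sort(unique(activity$frame))
  rankings <- lapply(frameIdx, function(f)
    rankFrame(activity[activity$frame == f, , drop = FALSE]))
  sv <- accumulateRankings(rankings)
  key <- paste(sv$ranks$frame, sv$ranks$id)
  activity$rank <- sv$ranks$rank[match(paste(activity$frame,
                                             activity$track_id), key)]
  act <- stats::setNames(sv$frameActive$active,
                         as.character(sv$frameActive$frame))
  activity$is_active <- as.integer(
    !is.na(act[as.character(activity$frame)]) &
      act[as.character(activity$frame)] == activity$track_id)
  list(scoreVectors = sv, activity = activity)
}
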