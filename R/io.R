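# On-disk formats. All tabular artifacts share one MOT-Challenge-style CSV
# dialect: comma-separated columns frame,id,x,y,w,h,conf,label[,active],
# header optional on read, always written. Frame indices are 1-based in
# files (MOT convention) and 0-based inside the package; the conversion
# happens here and only here.

motHeader <- c("frame", "id", "x", "y", "w", "h", "conf", "label")

#' Read per-frame detections (or ground truth) from CSV
#'
#' Expects comma-separated rows \code{frame,id,x,y,w,h,conf,label} with an
#' optional 9th \code{active} column (0/1, ground truth only) and an
#' optional header. Rows with non-numeric coordinates or non-positive width
#' or height are rejected with a warning naming the offending line numbers.
#' File frame indices are 1-based and converted to 0-based.
#'
#' @param path CSV file path.
#' @return A [DetectionSet-class]; ground-truth files keep their
#'   \code{active} column.
#' @export
readDetections <- function(path) {
  if (!file.exists(path)) stop("detection file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(DetectionSet())
  fields <- strsplit(lines, ",", fixed = TRUE)
  first <- suppressWarnings(as.numeric(fields[[1]][1]))
  start <- if (is.na(first)) 2L else 1L  # header present?
  if (start > length(lines)) return(DetectionSet())
  rows <- vector("list", length(lines) - start + 1L)
  bad <- integer()
  hasActive <- FALSE
  for (i in seq.int(start, length(lines))) {
    f <- trimws(fields[[i]])
    if (length(f) < 8L) { bad <- c(bad, i); next }
    num <- suppressWarnings(as.numeric(f[c(1:7, if (length(f) >= 9L) 9L)]))
    if (anyNA(num) || num[5] <= 0 || num[6] <= 0 || num[1] < 1) {
      bad <- c(bad, i); next
    }
    if (length(f) >= 9L) hasActive <- TRUE
    rows[[i - start + 1L]] <- data.frame(
      frame = as.integer(num[1]) - 1L, id = as.integer(num[2]),
      x = num[3], y = num[4], w = num[5], h = num[6], conf = num[7],
      label = f[8],
      active = if (length(f) >= 9L) as.integer(num[8]) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (length(bad) > 0L)
    warning(sprintf("rejected %d malformed row(s) in %s (line %s)",
                    length(bad), path, paste(bad, collapse = ", ")))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(DetectionSet())
  d <- do.call(rbind, rows)
  if (!hasActive) d$active <- NULL
  DetectionSet(d)
}

#' Write detections to CSV
#'
#' Inverse of [readDetections()]: writes the shared CSV dialect with a
#' header and 1-based frame indices.
#'
#' @param dets a [DetectionSet-class].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeDetections <- function(dets, path) {
  stopifnot(is(dets, "DetectionSet"))
  d <- dets@detections
  d$frame <- d$frame + 1L
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write tracks in the shared CSV dialect
#'
#' Tracks are serialised as one row per (frame, box) assignment with the
#' \code{id} column filled, \code{conf = 1} and label \code{"person"}.
#'
#' @param tracks a [TrackSet-class].
#' @param path file path.
#' @return \code{readTracks()} returns a [TrackSet-class].
#' @export
writeTracks <- function(tracks, path) {
  stopifnot(is(tracks, "TrackSet"))
  a <- tracks@assignments
  d <- data.frame(frame = a$frame + 1L, id = a$id, x = a$x, y = a$y,
                  w = a$w, h = a$h, conf = rep(1, nrow(a)),
                  label = rep("person", nrow(a)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path) {
  dets <- readDetections(path)
  d <- dets@detections
  TrackSet(d[, c("frame", "id", "x", "y", "w", "h")])
}

#' Load an image sequence as grayscale intensity matrices
#'
#' Accepts a directory of PNG frames (read in lexicographic order), a
#' character vector of file paths, or a list of in-memory frames
#' (passthrough with validation). Frames come back as matrices of
#' intensities in \[0, 1\]; RGB input is converted to luma with the fixed
#' weights (0.299, 0.587, 0.114). Mismatched frame sizes are an error.
#'
#' @param src directory, file paths, or list of matrices/arrays.
#' @return List of numeric matrices (rows = y, cols = x).
#' @export
loadFrames <- function(src) {
  if (is.character(src) && length(src) == 1L && dir.exists(src)) {
    src <- sort(list.files(src, pattern = "\\.png$", full.names = TRUE))
    if (length(src) == 0L) stop("no PNG frames found in directory")
  }
  if (is.character(src)) {
    frames <- lapply(src, function(p) toGray(png::readPNG(p)))
  } else if (is.list(src)) {
    frames <- lapply(src, toGray)
  } else {
    stop("src must be a directory, file paths, or a list of frames")
  }
  if (length(frames) == 0L) stop("empty frame sequence")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions")
  frames
}

toGray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L)
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    return(img[, , 1])
  }
  stop("frames must be 2-D matrices or RGB(A) arrays")
}

#' Write grayscale frames as a PNG directory
#'
#' @param frames list of intensity matrices in \[0, 1\].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeFrames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%05d.png", seq_along(frames)))
  for (i in seq_along(frames))
    png::writePNG(pmin(pmax(frames[[i]], 0), 1), paths[i])
  invisible(paths)
}

#' Read / write the per-frame activity table
#'
#' CSV with columns \code{frame, track_id, measure, value, rank, is_active}
#' (1-based frames on disk).
#'
#' @param activity data frame as produced by [computeActivity()] /
#'   [rankActivity()].
#' @param path file path.
#' @export
writeActivity <- function(activity, path) {
  a <- activity
  for (col in c("rank", "is_active"))
    if (is.null(a[[col]])) a[[col]] <- NA
  a$frame <- a$frame + 1L
  utils::write.csv(a[, c("frame", "track_id", "measure", "value", "rank",
                         "is_active")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeActivity
#' @export
readActivity <- function(path) {
  if (!file.exists(path)) stop("activity file not found: ", path)
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  a$frame <- as.integer(a$frame) - 1L
  a
}

# md5 of an arbitrary R object via a serialised temp file (manifest hashes)
objectHash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}
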