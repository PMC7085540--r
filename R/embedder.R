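# Appearance descriptors. The tracker takes any embedder function
# f(frame, box) -> unit-norm non-negative descriptor; the default is an
# intensity/colour histogram of the box crop, which is deterministic,
# training-free, and sufficient to separate subjects of distinct
# appearance.

#' Default appearance embedder: normalised crop histogram
#'
#' Computes a 128-element descriptor of the image region inside a box:
#' for grayscale frames a 128-bin intensity histogram on \[0, 1\]; for RGB
#' arrays three 42-bin per-channel histograms padded to length 128. The
#' descriptor is L2-normalised onto the unit hypersphere (entries are
#' non-negative, so the cosine distance to any other descriptor lies in
#' \[0, 1\]). Boxes are clipped to the frame; a zero-area crop after
#' clipping is an error.
#'
#' @param frame intensity matrix in \[0, 1\] (rows = y) or RGB array.
#' @param box a box (see [boxCentroid()]).
#' @param dim descriptor length (default 128).
#' @return Numeric unit-norm vector of length \code{dim}.
#' @export
defaultEmbedder <- function(frame, box, dim = 128L) {
  gray <- is.matrix(frame)
  nr <- dim(frame)[1]
  nc <- dim(frame)[2]
  px <- boxPixels(box, nr, nc)
  if (is.null(px)) stop("zero-area crop: box lies outside the frame")
  if (gray) {
    vals <- frame[px$rows, px$cols]
    counts <- tabulate(pmin(floor(vals * dim) + 1L, dim), nbins = dim)
    desc <- as.numeric(counts)
  } else {
    bins <- dim %/% 3L
    desc <- numeric(dim)
    for (ch in 1:3) {
      vals <- frame[px$rows, px$cols, ch]
      counts <- tabulate(pmin(floor(vals * bins) + 1L, bins), nbins = bins)
      desc[seq.int((ch - 1L) * bins + 1L, ch * bins)] <- counts
    }
  }
  n2 <- sqrt(sum(desc^2))
  if (n2 == 0) stop("empty crop histogram")
  desc / n2
}

#' Cosine appearance distance to a descriptor gallery
#'
#' The visual term of the Deep-SORT-style cost: the minimum over a track's
#' gallery of one minus the dot product with the query descriptor. With
#' unit-norm, non-negative descriptors the result lies in \[0, 1\]; it is 0
#' when the gallery contains the query itself.
#'
#' @param gallery list (or matrix rows) of unit-norm descriptors; the
#'   track's most recent appearance history.
#' @param r query descriptor (unit norm).
#' @return Minimum cosine distance in \[0, 1\].
#' @export
appearanceDistance <- function(gallery, r) {
  if (is.list(gallery)) {
    if (length(gallery) == 0L) stop("empty appearance gallery")
    gallery <- do.call(rbind, gallery)
  }
  if (!is.matrix(gallery) || nrow(gallery) == 0L)
    stop("empty appearance gallery")
  min(1 - as.numeric(gallery %*% r))
}
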