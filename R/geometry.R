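# Axis-aligned bounding-box geometry. The coordinate convention throughout
# the package: origin at the image top-left, x rightward, y downward,
# 0-based, boxes half-open [x, x+w) x [y, y+h). Boxes are continuous; pixel
# (r, c) of a frame matrix covers [c-1, c) x [r-1, r).

#' Create a bounding box
#'
#' A box is a named numeric vector \code{c(x, y, w, h)}: top-left corner
#' offsets in pixels plus strictly positive width and height. The derived
#' centroid is \code{(x + w/2, y + h/2)} and the area \code{w * h}.
#'
#' @param x,y top-left corner offsets in pixels (0-based, x rightward,
#'   y downward).
#' @param w,h box width and height in pixels; must be > 0.
#' @return Named numeric vector of length 4.
#' @examples
#' b <- bbox(0, 0, 10, 10)
#' boxCentroid(b)
#' boxArea(b)
#' @export
bbox <- function(x, y, w, h) {
  v <- c(x = as.numeric(x), y = as.numeric(y),
         w = as.numeric(w), h = as.numeric(h))
  if (any(!is.finite(v))) stop("box coordinates must be finite")
  if (v[["w"]] <= 0 || v[["h"]] <= 0) stop("box width and height must be > 0")
  v
}

# Coerce boxes to an n x 4 matrix with columns x, y, w, h. Accepts a numeric
# vector of length 4, a matrix, or a data frame with x/y/w/h columns.
asBoxMatrix <- function(b) {
  if (is.numeric(b) && is.null(dim(b)) && length(b) == 4L) {
    m <- matrix(b, nrow = 1L)
  } else if (is.matrix(b) && ncol(b) == 4L) {
    m <- b
  } else if (is.data.frame(b) && all(c("x", "y", "w", "h") %in% names(b))) {
    m <- as.matrix(b[, c("x", "y", "w", "h")])
  } else {
    stop("cannot interpret object as bounding box(es)")
  }
  colnames(m) <- c("x", "y", "w", "h")
  if (any(m[, "w"] <= 0) || any(m[, "h"] <= 0))
    stop("box width and height must be > 0")
  m
}

#' Box centroid and area
#'
#' @param b a box (length-4 vector), an n x 4 matrix, or a data frame with
#'   columns \code{x, y, w, h}.
#' @return \code{boxCentroid}: an n x 2 matrix of \code{(cx, cy)};
#'   \code{boxArea}: a numeric vector of areas in square pixels.
#' @export
boxCentroid <- function(b) {
  m <- asBoxMatrix(b)
  cbind(cx = m[, "x"] + m[, "w"] / 2, cy = m[, "y"] + m[, "h"] / 2)
}

#' @rdname boxCentroid
#' @export
boxArea <- function(b) {
  m <- asBoxMatrix(b)
  unname(m[, "w"] * m[, "h"])
}

#' Euclidean distance between box centroids
#'
#' The spatial term of the Hungarian tracking cost: the Euclidean (L2)
#' distance in pixels between the centroids of two boxes. Vectorised
#' row-wise when given matrices of equal row count (or one box against
#' many).
#'
#' @param a,b boxes as in [boxCentroid()].
#' @return Numeric vector of distances in pixels; symmetric and >= 0.
#' @examples
#' centroidDistance(bbox(5, 5, 10, 10), bbox(8, 9, 10, 10)) # 5
#' @export
centroidDistance <- function(a, b) {
  ca <- boxCentroid(a)
  cb <- boxCentroid(b)
  if (nrow(ca) == 1L && nrow(cb) > 1L) ca <- ca[rep(1L, nrow(cb)), , drop = FALSE]
  if (nrow(cb) == 1L && nrow(ca) > 1L) cb <- cb[rep(1L, nrow(ca)), , drop = FALSE]
  unname(sqrt(rowSums((ca - cb)^2)))
}

#' Intersection over union of two boxes
#'
#' Computed on continuous box geometry (no pixel quantisation): the ratio of
#' the intersection area to the union area of two axis-aligned boxes.
#' Returns 0 for disjoint boxes and 1 iff the boxes are identical.
#'
#' @param a,b boxes as in [boxCentroid()]; vectorised row-wise.
#' @return Numeric vector of ratios in \[0, 1\].
#' @examples
#' boxIoU(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10)) # 1/3
#' @export
boxIoU <- function(a, b) {
  ma <- asBoxMatrix(a)
  mb <- asBoxMatrix(b)
  if (nrow(ma) == 1L && nrow(mb) > 1L) ma <- ma[rep(1L, nrow(mb)), , drop = FALSE]
  if (nrow(mb) == 1L && nrow(ma) > 1L) mb <- mb[rep(1L, nrow(ma)), , drop = FALSE]
  ix <- pmax(0, pmin(ma[, "x"] + ma[, "w"], mb[, "x"] + mb[, "w"]) -
                pmax(ma[, "x"], mb[, "x"]))
  iy <- pmax(0, pmin(ma[, "y"] + ma[, "h"], mb[, "y"] + mb[, "h"]) -
                pmax(ma[, "y"], mb[, "y"]))
  inter <- ix * iy
  uni <- ma[, "w"] * ma[, "h"] + mb[, "w"] * mb[, "h"] - inter
  unname(ifelse(inter > 0, inter / uni, 0))
}

# Intersect a box with the frame rectangle [0, width) x [0, height); returns
# NULL when nothing remains.
clipBox <- function(b, width, height) {
  m <- asBoxMatrix(b)[1L, ]
  x0 <- max(m[["x"]], 0)
  y0 <- max(m[["y"]], 0)
  x1 <- min(m[["x"]] + m[["w"]], width)
  y1 <- min(m[["y"]] + m[["h"]], height)
  if (x1 - x0 <= 0 || y1 - y0 <= 0) return(NULL)
  c(x = x0, y = y0, w = x1 - x0, h = y1 - y0)
}

# Pixel index ranges (1-based matrix rows/cols) covered by a box in a frame
# of the given dimensions; NULL when the box misses the frame entirely.
boxPixels <- function(b, nrowFrame, ncolFrame) {
  m <- asBoxMatrix(b)[1L, ]
  cols <- seq.int(max(1L, floor(m[["x"]]) + 1L),
                  min(ncolFrame, ceiling(m[["x"]] + m[["w"]])))
  rows <- seq.int(max(1L, floor(m[["y"]]) + 1L),
                  min(nrowFrame, ceiling(m[["y"]] + m[["h"]])))
  if (length(cols) == 0L || length(rows) == 0L ||
      m[["x"]] >= ncolFrame || m[["y"]] >= nrowFrame ||
      m[["x"]] + m[["w"]] <= 0 || m[["y"]] + m[["h"]] <= 0) return(NULL)
  list(rows = rows, cols = cols)
}
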