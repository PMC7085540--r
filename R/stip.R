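# Harris3D spatiotemporal interest points. A scale-space representation L
# of the frame volume is built by separable Gaussian smoothing with
# independent spatial and temporal variances; the second-moment matrix mu
# of the first-order derivatives of L, averaged at the integration scales,
# yields the corner function H = det(mu) - k * trace(mu)^3 whose strict
# local maxima over the 26-connected (x, y, t) neighbourhood are the
# interest points.

#' Detect spatiotemporal interest points (Harris3D)
#'
#' @param volume a 3-D array (rows = y, cols = x, slices = t) of
#'   intensities, or a list of frame matrices. At least 3 frames.
#' @param sigma2 spatial variance of the smoothing kernel (default 4).
#' @param tau2 temporal variance (default 2).
#' @param s integration-scale factor: the second-moment matrix entries are
#'   averaged with variances \code{s * sigma2} and \code{s * tau2}
#'   (default 2).
#' @param k corner-function parameter (default 0.005).
#' @param threshold minimum corner response H of a reported point (default
#'   1e-13 for unit-range intensities).
#' @return Data frame with one row per interest point: 0-based \code{x},
#'   \code{y}, \code{t} coordinates and the \code{response} H. A temporally
#'   constant volume yields no points (the temporal derivative vanishes, so
#'   H <= 0 everywhere).
#' @details Detection is single-scale (no scale selection); maxima are
#'   sought at interior voxels only (a 1-voxel margin in every direction).
#'   Smoothing and derivatives use edge-replicated padding; the temporal
#'   derivative is one-sided at the first and last frame.
#' @export
harris3d <- function(volume, sigma2 = 4, tau2 = 2, s = 2, k = 0.005,
                     threshold = 1e-13) {
  v <- asVolume(volume)
  if (dim(v)[3] < 3L) stop("need at least 3 frames for Harris3D")
  H <- harris3dResponse(v, sigma2, tau2, s, k)
  localMaxima3d(H, threshold)
}

asVolume <- function(volume) {
  if (is.list(volume)) {
    dims <- vapply(volume, dim, integer(2))
    if (any(dims != dims[, 1])) stop("all frames must share dimensions")
    array(unlist(volume), dim = c(dims[1, 1], dims[2, 1], length(volume)))
  } else if (is.array(volume) && length(dim(volume)) == 3L) {
    volume
  } else {
    stop("volume must be a 3-D array or a list of matrices")
  }
}

# Dense corner-response volume H (same dimensions as the input).
harris3dResponse <- function(v, sigma2 = 4, tau2 = 2, s = 2, k = 0.005) {
  ks <- gaussKernel(sqrt(sigma2))
  kt <- gaussKernel(sqrt(tau2))
  L <- convDim(convDim(convDim(v, ks, 1L), ks, 2L), kt, 3L)
  Lx <- derivDim(L, 2L)
  Ly <- derivDim(L, 1L)
  Lt <- derivDim(L, 3L)
  kis <- gaussKernel(sqrt(s * sigma2))
  kit <- gaussKernel(sqrt(s * tau2))
  sm <- function(a) convDim(convDim(convDim(a, kis, 1L), kis, 2L), kit, 3L)
  m11 <- sm(Lx * Lx); m22 <- sm(Ly * Ly); m33 <- sm(Lt * Lt)
  m12 <- sm(Lx * Ly); m13 <- sm(Lx * Lt); m23 <- sm(Ly * Lt)
  detMu <- m11 * (m22 * m33 - m23 * m23) -
           m12 * (m12 * m33 - m23 * m13) +
           m13 * (m12 * m23 - m22 * m13)
  trMu <- m11 + m22 + m33
  detMu - k * trMu^3
}

# Strict 26-neighbourhood local maxima of a 3-D response volume above a
# threshold, interior voxels only.
localMaxima3d <- function(H, threshold) {
  d <- dim(H)
  mask <- H > threshold
  # exclude the boundary shell
  mask[c(1L, d[1]), , ] <- FALSE
  mask[, c(1L, d[2]), ] <- FALSE
  mask[, , c(1L, d[3])] <- FALSE
  if (any(mask)) {
    for (dz in -1:1) for (dyy in -1:1) for (dxx in -1:1) {
      if (dz == 0L && dyy == 0L && dxx == 0L) next
      nb <- shiftDim(shiftDim(shiftDim(H, dyy, 1L), dxx, 2L), dz, 3L)
      mask <- mask & (H > nb)
      if (!any(mask)) break
    }
  }
  idx <- which(mask, arr.ind = TRUE)
  data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1, t = idx[, 3] - 1,
             response = H[mask])
}

#' Interest-point density activity of a box
#'
#' The number of spatiotemporal interest points inside the box at the given
#' frame, divided by the box area — the STIP-density activity measure.
#' Interest points are attributed to their nearest integer frame.
#'
#' @param box a box (see [boxCentroid()]).
#' @param stips data frame from [harris3d()].
#' @param frame 0-based frame index; when NULL, \code{stips} is assumed
#'   already filtered to one frame.
#' @return Non-negative density (points per square pixel).
#' @examples
#' pts <- data.frame(x = c(1, 5, 10, 30), y = c(1, 5, 10, 5), t = 0,
#'                   response = 1)
#' activitySTIP(bbox(0, 0, 20, 25), pts, frame = 0) # 3 / 500
#' @export
activitySTIP <- function(box, stips, frame = NULL) {
  m <- asBoxMatrix(box)[1L, ]
  if (!is.null(frame)) stips <- stips[round(stips$t) == frame, , drop = FALSE]
  inside <- stips$x >= m[["x"]] & stips$x < m[["x"]] + m[["w"]] &
            stips$y >= m[["y"]] & stips$y < m[["y"]] + m[["h"]]
  sum(inside) / (m[["w"]] * m[["h"]])
}
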