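# Constant-velocity linear-Gaussian (Kalman) filter on the measurement
# (cx, cy, aspect, height), the Deep-SORT parameterisation: state is the
# measurement plus its velocities, noise scales with the box height, time
# step is one frame. The velocity process noise is set an order higher
# than the pedestrian-tracking default (1/20 of the height rather than
# 1/160): the subjects this pipeline singles out make sudden speed and
# direction changes, and a stiffer filter would gate them out of their own
# track at every reversal.

kfSigmaPos <- 1 / 20
kfSigmaVel <- 1 / 20

# box (x, y, w, h) -> measurement (cx, cy, aspect = w/h, h)
boxToMeasurement <- function(b) {
  m <- asBoxMatrix(b)[1L, ]
  c(m[["x"]] + m[["w"]] / 2, m[["y"]] + m[["h"]] / 2,
    m[["w"]] / m[["h"]], m[["h"]])
}

measurementToBox <- function(z) {
  w <- z[3] * z[4]
  bbox(z[1] - w / 2, z[2] - z[4] / 2, w, z[4])
}

kfInit <- function(z) {
  h <- z[4]
  std <- c(2 * kfSigmaPos * h, 2 * kfSigmaPos * h, 1e-2, 2 * kfSigmaPos * h,
           10 * kfSigmaVel * h, 10 * kfSigmaVel * h, 1e-5, 10 * kfSigmaVel * h)
  list(mean = c(z, rep(0, 4)), cov = diag(std^2))
}

kfPredict <- function(kf) {
  h <- kf$mean[4]
  Fm <- diag(8)
  Fm[cbind(1:4, 5:8)] <- 1
  stdPos <- c(kfSigmaPos * h, kfSigmaPos * h, 1e-2, kfSigmaPos * h)
  stdVel <- c(kfSigmaVel * h, kfSigmaVel * h, 1e-5, kfSigmaVel * h)
  Q <- diag(c(stdPos, stdVel)^2)
  list(mean = as.numeric(Fm %*% kf$mean),
       cov = Fm %*% kf$cov %*% t(Fm) + Q)
}

# project the state into measurement space: mean y and innovation cov S
kfProject <- function(kf) {
  h <- kf$mean[4]
  std <- c(kfSigmaPos * h, kfSigmaPos * h, 1e-1, kfSigmaPos * h)
  H <- cbind(diag(4), matrix(0, 4, 4))
  list(mean = as.numeric(H %*% kf$mean),
       cov = H %*% kf$cov %*% t(H) + diag(std^2))
}

kfUpdate <- function(kf, z) {
  proj <- kfProject(kf)
  H <- cbind(diag(4), matrix(0, 4, 4))
  K <- kf$cov %*% t(H) %*% solve(proj$cov)
  innov <- z - proj$mean
  list(mean = as.numeric(kf$mean + K %*% innov),
       cov = kf$cov - K %*% H %*% kf$cov)
}

#' Squared Mahalanobis distance between a predicted state and a detection
#'
#' The spatial term of the Deep-SORT-style cost: the quadratic form
#' \code{t(d - y) S^-1 (d - y)} between the predicted measurement-space mean
#' \code{y} (with innovation covariance \code{S}) and the detection's
#' measurement \code{(cx, cy, aspect, height)}. Zero iff the detection
#' equals the prediction.
#'
#' @param mean predicted measurement-space mean (length 4), or a list with
#'   elements \code{mean} and \code{cov} (in which case \code{cov} may be
#'   missing).
#' @param cov innovation covariance (4 x 4, symmetric positive-definite).
#' @param det a box (see [boxCentroid()]) or a raw measurement vector of
#'   length 4.
#' @return Non-negative squared distance.
#' @examples
#' mahalanobisDistance(c(0, 0, 0, 0), 4 * diag(4), c(2, 0, 0, 0)) # 1
#' @export
mahalanobisDistance <- function(mean, cov, det) {
  if (is.list(mean)) {
    cov <- mean$cov
    mean <- mean$mean
  }
  z <- if (is.numeric(det) && is.null(dim(det)) && length(det) == 4L &&
           !all(c("x", "y", "w", "h") %in% names(det))) det
       else boxToMeasurement(det)
  d <- z - mean
  ch <- tryCatch(chol(cov), error = function(e)
    stop("covariance matrix is not positive-definite"))
  y <- backsolve(ch, d, transpose = TRUE)
  sum(y^2)
}
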