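# Block Lucas-Kanade optical flow. The frame is divided into square
# sections; all pixels of a section are assumed to share one velocity,
# which is estimated by least squares over a larger centred aggregation
# window and refined by Newton iterations with bilinear warping (the
# original iterative Lucas-Kanade scheme; a single linearisation cannot
# recover shifts much beyond one pixel). The first linearised pass is
# evaluated for every section at once via integral images; only sections
# whose initial estimate indicates real motion enter the per-section
# refinement loop.

#' Estimate block-wise optical flow between two frames
#'
#' Returns the velocity field from \code{frameA} to \code{frameB} in
#' pixels/frame: one vector per \code{block} x \code{block} section,
#' replicated to pixel resolution. Each section's vector is the iterative
#' least-squares Lucas-Kanade estimate over a \code{window} x \code{window}
#' aggregation window centred on the section; pixels whose warped position
#' falls outside the frame are excluded from the normal equations.
#' Rank-deficient windows (untextured regions) yield a zero vector and are
#' counted in the \code{degenerate} field.
#'
#' @param frameA,frameB intensity matrices of identical size, values in
#'   \[0, 1\].
#' @param block section size in pixels (default 8).
#' @param window aggregation window in pixels (default 16).
#' @param maxIter Newton refinement iteration cap (default 5).
#' @param tol stop when the update falls below this many pixels (0.01).
#' @param search integer block-matching pre-search radius in pixels
#'   (default 4): sections flagged as moving seed the Newton iterations
#'   from the best integer displacement, which keeps the refinement inside
#'   its convergence basin for displacements beyond the texture
#'   correlation length.
#' @return A \code{FlowField}: list with full-resolution matrices \code{vx}
#'   and \code{vy}, the \code{block} size, and the \code{degenerate} block
#'   count.
#' @export
lucasKanadeFlow <- function(frameA, frameB, block = 8L, window = 16L,
                            maxIter = 5L, tol = 0.01, search = 4L) {
  stopifnot(is.matrix(frameA), is.matrix(frameB),
            all(dim(frameA) == dim(frameB)))
  ny <- nrow(frameA)
  nx <- ncol(frameA)
  Ix <- derivDim(frameA, 2L)
  Iy <- derivDim(frameA, 1L)
  It0 <- frameB - frameA
  half <- max(0L, (window - block) %/% 2L)
  rStarts <- seq.int(1L, ny, by = block)
  cStarts <- seq.int(1L, nx, by = block)
  r1 <- pmin(rStarts + block - 1L, ny)
  c1 <- pmin(cStarts + block - 1L, nx)
  wr0 <- pmax(1L, rStarts - half); wr1 <- pmin(ny, r1 + half)
  wc0 <- pmax(1L, cStarts - half); wc1 <- pmin(nx, c1 + half)
  # windowed sums of the normal-equation terms via integral images
  rect <- function(img) {
    S <- matrix(0, ny + 1L, nx + 1L)
    S[-1L, -1L] <- t(apply(apply(img, 2L, cumsum), 1L, cumsum))
    S[wr1 + 1L, wc1 + 1L] - S[wr0, wc1 + 1L] -
      S[wr1 + 1L, wc0] + S[wr0, wc0]
  }
  A11 <- rect(Ix * Ix)
  A12 <- rect(Ix * Iy)
  A22 <- rect(Iy * Iy)
  B1 <- rect(Ix * It0)
  B2 <- rect(Iy * It0)
  det <- A11 * A22 - A12 * A12
  good <- is.finite(det) & det > 1e-12 & A11 > 1e-12 & A22 > 1e-12
  v0x <- ifelse(good, (A12 * B2 - A22 * B1) / det, 0)
  v0y <- ifelse(good, (A12 * B1 - A11 * B2) / det, 0)
  degenerate <- sum(!good)
  # refine sections showing motion: a non-trivial first estimate or a
  # temporal residual well above the noise floor
  meanAbsIt <- rect(abs(It0)) / rect(matrix(1, ny, nx))
  refine <- good & (abs(v0x) > 0.2 | abs(v0y) > 0.2 | meanAbsIt > 0.03)
  if (maxIter > 1L && any(refine)) {
    offs <- seq.int(-search, search)
    offs <- offs[order(abs(offs))]       # ties prefer the smaller shift
    for (bi in which(refine)) {
      i <- (bi - 1L) %% length(rStarts) + 1L
      j <- (bi - 1L) %/% length(rStarts) + 1L
      wr <- seq.int(wr0[i], wr1[i])
      wc <- seq.int(wc0[j], wc1[j])
      gx <- as.numeric(Ix[wr, wc])
      gy <- as.numeric(Iy[wr, wc])
      tmplM <- frameA[wr, wc]
      tmpl <- as.numeric(tmplM)
      xs0 <- rep(wc, each = length(wr))
      ys0 <- rep(wr, times = length(wc))
      newton <- function(v) {
        res <- Inf
        for (it in seq_len(maxIter - 1L)) {
          xs <- xs0 + v[1]
          ys <- ys0 + v[2]
          # pixels warped outside the frame carry no information
          ok <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
          if (sum(ok) < 6L) return(list(v = c(0, 0), res = Inf, bad = TRUE))
          G <- matrix(c(sum(gx[ok]^2), sum(gx[ok] * gy[ok]),
                        sum(gx[ok] * gy[ok]), sum(gy[ok]^2)), 2L, 2L)
          dG <- G[1, 1] * G[2, 2] - G[1, 2]^2
          if (!is.finite(dG) || dG < 1e-12)
            return(list(v = c(0, 0), res = Inf, bad = TRUE))
          It <- sampleBilinear(frameB, xs[ok], ys[ok]) - tmpl[ok]
          res <- mean(abs(It))
          b <- -c(sum(gx[ok] * It), sum(gy[ok] * It))
          dv <- solve(G, b)
          v <- v + dv
          if (any(!is.finite(v)))
            return(list(v = c(0, 0), res = Inf, bad = TRUE))
          if (max(abs(dv)) < tol) break
        }
        list(v = v, res = res, bad = FALSE)
      }
      fit <- newton(c(v0x[bi], v0y[bi]))
      if (fit$res > 0.03) {
        # the linearised start missed the basin: integer block-matching
        # pre-search, then refine again
        best <- c(0, 0)
        bestSSD <- Inf
        for (dy2 in offs) for (dx2 in offs) {
          fb <- frameB[pmin(pmax(wr + dy2, 1L), ny),
                       pmin(pmax(wc + dx2, 1L), nx)]
          ssd <- mean((fb - tmplM)^2)
          if (ssd < bestSSD - 1e-12) {
            bestSSD <- ssd
            best <- c(dx2, dy2)
          }
        }
        fit2 <- newton(best)
        if (fit2$res < fit$res) fit <- fit2
      }
      if (fit$bad) {
        degenerate <- degenerate + 1L
        fit$v <- c(0, 0)
      }
      v0x[bi] <- fit$v[1]
      v0y[bi] <- fit$v[2]
    }
  }
  # replicate section vectors to pixel resolution
  rowBlock <- findInterval(seq_len(ny), rStarts)
  colBlock <- findInterval(seq_len(nx), cStarts)
  vx <- matrix(v0x[cbind(rep(rowBlock, times = nx),
                         rep(colBlock, each = ny))], ny, nx)
  vy <- matrix(v0y[cbind(rep(rowBlock, times = nx),
                         rep(colBlock, each = ny))], ny, nx)
  structure(list(vx = vx, vy = vy, block = as.integer(block),
                 degenerate = degenerate),
            class = "FlowField")
}

# bilinear interpolation of img at continuous (x = col, y = row)
# coordinates, clamped to the image
sampleBilinear <- function(img, xs, ys) {
  ny <- nrow(img)
  nx <- ncol(img)
  xs <- pmin(pmax(xs, 1), nx)
  ys <- pmin(pmax(ys, 1), ny)
  x0 <- pmin(floor(xs), nx - 1L)
  y0 <- pmin(floor(ys), ny - 1L)
  fx <- xs - x0
  fy <- ys - y0
  (1 - fy) * ((1 - fx) * img[cbind(y0, x0)] + fx * img[cbind(y0, x0 + 1L)]) +
    fy * ((1 - fx) * img[cbind(y0 + 1L, x0)] + fx * img[cbind(y0 + 1L, x0 + 1L)])
}

#' Flow magnitude image
#'
#' @param flow a \code{FlowField} from [lucasKanadeFlow()].
#' @return Matrix of per-pixel speeds \code{sqrt(vx^2 + vy^2)}.
#' @export
flowMagnitude <- function(flow) {
  sqrt(flow$vx^2 + flow$vy^2)
}

#' Optical-flow activity of a box
#'
#' The maximum flow magnitude over the pixels inside the box — the
#' optical-flow activity measure of a detected subject. The maximum (rather
#' than the mean) keeps values comparable across box sizes.
#'
#' @param box a box (see [boxCentroid()]).
#' @param flow a \code{FlowField} covering the frame.
#' @return Non-negative activity value in pixels/frame.
#' @export
activityOF <- function(box, flow) {
  px <- boxPixels(box, nrow(flow$vx), ncol(flow$vx))
  if (is.null(px)) stop("box lies fully outside the frame")
  max(sqrt(flow$vx[px$rows, px$cols]^2 + flow$vy[px$rows, px$cols]^2))
}

#' @export
print.FlowField <- function(x, ...) {
  cat(sprintf("FlowField %dx%d px (block %d), speed max %.3f px/frame, %d degenerate block(s)\n",
              ncol(x$vx), nrow(x$vx), x$block, max(flowMagnitude(x)),
              x$degenerate))
  invisible(x)
}
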