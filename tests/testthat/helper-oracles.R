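# Independent oracles and fixture builders used across the suite.

# Exhaustive-search assignment oracle: over all one-to-one partial
# matchings restricted to finite-cost pairs, maximise the number of
# matches, then minimise total cost.
bruteForceAssignment <- function(cost) {
  nr <- nrow(cost)
  nc <- ncol(cost)
  best <- list(k = 0L, cost = 0)
  rec <- function(i, usedC, k, tot) {
    if (i > nr) {
      if (k > best$k || (k == best$k && tot < best$cost - 1e-12))
        best <<- list(k = k, cost = tot)
      return(invisible(NULL))
    }
    rec(i + 1L, usedC, k, tot)
    for (j in seq_len(nc)) {
      if (!usedC[j] && is.finite(cost[i, j])) {
        usedC[j] <- TRUE
        rec(i + 1L, usedC, k + 1L, tot + cost[i, j])
        usedC[j] <- FALSE
      }
    }
  }
  if (nr > 0L && nc > 0L) rec(1L, logical(nc), 0L, 0)
  best
}

# Pixel-grid counting oracle for IoU: count covered cells on a fine grid.
pixelGridIoU <- function(a, b, step = 0.25) {
  x0 <- min(a[1], b[1]) - 1
  x1 <- max(a[1] + a[3], b[1] + b[3]) + 1
  y0 <- min(a[2], b[2]) - 1
  y1 <- max(a[2] + a[4], b[2] + b[4]) + 1
  xs <- seq(x0 + step / 2, x1, by = step)
  ys <- seq(y0 + step / 2, y1, by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inA <- gx >= a[1] & gx < a[1] + a[3] & gy >= a[2] & gy < a[2] + a[4]
  inB <- gx >= b[1] & gx < b[1] + b[3] & gy >= b[2] & gy < b[2] + b[4]
  if (!any(inA & inB)) return(0)
  sum(inA & inB) / sum(inA | inB)
}

# Smoothed random texture (the standard flow/STIP test pattern).
mkSmoothTexture <- function(nr, nc = nr, seed = 3, sigma = 1.5) {
  set.seed(seed)
  m <- matrix(runif(nr * nc), nr, nc)
  k <- dnorm(seq(-ceiling(3 * sigma), ceiling(3 * sigma)), sd = sigma)
  k <- k / sum(k)
  pad <- function(v, n) pmin(pmax(v, 1), n)
  out <- matrix(0, nr, nc)
  for (i in seq_along(k))
    out <- out + k[i] * m[pad(seq_len(nr) + i - 1 - (length(k) - 1) / 2, nr), ]
  m <- out
  out <- matrix(0, nr, nc)
  for (i in seq_along(k))
    out <- out + k[i] * m[, pad(seq_len(nc) + i - 1 - (length(k) - 1) / 2, nc)]
  out
}

# A pure-translation frame pair cut from a larger texture (no wrap seam):
# cropping the second frame at -d moves the content by +d.
translatedPair <- function(big, n, margin, dx, dy) {
  list(a = big[margin + seq_len(n), margin + seq_len(n)],
       b = big[margin - dy + seq_len(n), margin - dx + seq_len(n)])
}

# A small volume with an abrupt-appearance event (guaranteed interior
# spatiotemporal structure for maxima-matching tests).
eventVolume <- function(d = c(16L, 16L, 8L), onset = 4L, seed = 17) {
  set.seed(seed)
  v <- array(0.2 + 0.05 * runif(prod(d)), d)
  cy <- d[1] %/% 2; cx <- d[2] %/% 2
  patch <- matrix(0.6 + 0.35 * runif(25), 5, 5)
  for (t in seq.int(onset + 1L, d[3]))
    v[cy + (-2:2), cx + (-2:2), t] <- patch
  v
}

# Direct dense Harris3D oracle: full (non-separable) 3-D Gaussian kernels
# applied by explicit shift-and-add over every kernel tap, clamped
# (edge-replicated) indexing, central differences with one-sided ends.
# Independent of the package's separable implementation.
denseHarrisOracle <- function(v, sigma2 = 4, tau2 = 2, s = 2, k = 0.005) {
  d <- dim(v)
  kern1 <- function(sd) {
    h <- max(1L, ceiling(3 * sd))
    w <- dnorm(seq(-h, h), sd = sd)
    w / sum(w)
  }
  smooth <- function(a, ks, kt) {
    hs <- (length(ks) - 1L) / 2L
    ht <- (length(kt) - 1L) / 2L
    out <- array(0, d)
    for (iy in seq_along(ks)) for (ix in seq_along(ks)) for (it in seq_along(kt)) {
      wgt <- ks[iy] * ks[ix] * kt[it]
      ry <- pmin(pmax(seq_len(d[1]) + iy - 1L - hs, 1L), d[1])
      rx <- pmin(pmax(seq_len(d[2]) + ix - 1L - hs, 1L), d[2])
      rt <- pmin(pmax(seq_len(d[3]) + it - 1L - ht, 1L), d[3])
      out <- out + wgt * a[ry, rx, rt]
    }
    out
  }
  deriv <- function(a, dim) {
    n <- d[dim]
    pick <- function(idx) {
      if (dim == 1L) a[pmin(pmax(idx, 1L), n), , , drop = FALSE]
      else if (dim == 2L) a[, pmin(pmax(idx, 1L), n), , drop = FALSE]
      else a[, , pmin(pmax(idx, 1L), n), drop = FALSE]
    }
    out <- (pick(seq_len(n) + 1L) - pick(seq_len(n) - 1L)) / 2
    setSlice <- function(x, idx, val) {
      if (dim == 1L) x[idx, , ] <- val
      else if (dim == 2L) x[, idx, ] <- val
      else x[, , idx] <- val
      x
    }
    out <- setSlice(out, 1L, pick(2L) - pick(1L))
    out <- setSlice(out, n, pick(n) - pick(n - 1L))
    out
  }
  ks <- kern1(sqrt(sigma2)); kt <- kern1(sqrt(tau2))
  L <- smooth(v, ks, kt)
  Lx <- deriv(L, 2L); Ly <- deriv(L, 1L); Lt <- deriv(L, 3L)
  kis <- kern1(sqrt(s * sigma2)); kit <- kern1(sqrt(s * tau2))
  m11 <- smooth(Lx * Lx, kis, kit); m22 <- smooth(Ly * Ly, kis, kit)
  m33 <- smooth(Lt * Lt, kis, kit); m12 <- smooth(Lx * Ly, kis, kit)
  m13 <- smooth(Lx * Lt, kis, kit); m23 <- smooth(Ly * Lt, kis, kit)
  m11 * (m22 * m33 - m23^2) - m12 * (m12 * m33 - m23 * m13) +
    m13 * (m12 * m23 - m22 * m13) - k * (m11 + m22 + m33)^3
}

# The worked rank-aggregation example: per-frame rankings of four tracks
# over five frames (the fourth frame has two tracks tied at the top, which
# suppresses that frame's active flag but counts for both score vectors).
table1Rankings <- function() {
  mk <- function(frame, ids, ranks) {
    structure(list(frame = frame,
                   ranks = setNames(as.integer(ranks), as.character(ids)),
                   winners = as.integer(ids[ranks == 1L]),
                   active = if (sum(ranks == 1L) == 1L)
                     as.integer(ids[ranks == 1L]) else NA_integer_),
              class = "FrameRanking")
  }
  list(mk(0L, c(1, 2, 6), c(2, 3, 1)),
       mk(1L, c(1, 2, 6), c(2, 3, 1)),
       mk(2L, c(2, 6), c(2, 1)),
       mk(3L, c(1, 2, 6, 9), c(1, 3, 1, 2)),
       mk(4L, c(6, 9), c(1, 2)))
}

# A compact scene for fast end-to-end tests.
smallSceneConfig <- function(seed = 1, nFrames = 30L) {
  sceneConfig(frameWidth = 120L, frameHeight = 96L, nFrames = nFrames,
              nSprites = 3L, seed = seed)
}
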