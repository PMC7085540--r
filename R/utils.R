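# Internal array helpers shared by the flow and STIP code. All padding is
# edge-replicated (index clamping) so smoothing and differentiation behave
# sensibly at frame and sequence boundaries.

# discrete Gaussian kernel truncated at +/- 3 sd, normalised to unit sum
gaussKernel <- function(sd) {
  stopifnot(sd > 0)
  h <- max(1L, ceiling(3 * sd))
  w <- stats::dnorm(seq(-h, h), sd = sd)
  w / sum(w)
}

# extract a slice of a 2-D or 3-D array along `dim` using an index vector
sliceIndex <- function(a, dim, idx) {
  nd <- length(dim(a))
  if (nd == 2L) {
    if (dim == 1L) a[idx, , drop = FALSE] else a[, idx, drop = FALSE]
  } else if (nd == 3L) {
    if (dim == 1L) a[idx, , , drop = FALSE]
    else if (dim == 2L) a[, idx, , drop = FALSE]
    else a[, , idx, drop = FALSE]
  } else {
    stop("only 2-D and 3-D arrays are supported")
  }
}

# shift along `dim` by `off` with edge replication
shiftDim <- function(a, off, dim) {
  n <- dim(a)[dim]
  idx <- pmin(pmax(seq_len(n) + off, 1L), n)
  sliceIndex(a, dim, idx)
}

# 1-D convolution along `dim` with an odd symmetric-support kernel,
# edge-replicated padding
convDim <- function(a, w, dim) {
  h <- (length(w) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (k in seq_along(w)) {
    out <- out + w[k] * shiftDim(a, k - 1L - h, dim)
  }
  out
}

# central difference along `dim`; boundary slices use one-sided differences
derivDim <- function(a, dim) {
  n <- dim(a)[dim]
  if (n < 2L) stop("need at least 2 samples along the differentiated axis")
  out <- (shiftDim(a, 1L, dim) - shiftDim(a, -1L, dim)) / 2
  # one-sided at the two ends
  asgn <- function(x, idx, val) {
    nd <- length(dim(x))
    if (nd == 2L) {
      if (dim == 1L) x[idx, ] <- val else x[, idx] <- val
    } else {
      if (dim == 1L) x[idx, , ] <- val
      else if (dim == 2L) x[, idx, ] <- val
      else x[, , idx] <- val
    }
    x
  }
  first <- sliceIndex(a, dim, 2L) - sliceIndex(a, dim, 1L)
  last <- sliceIndex(a, dim, n) - sliceIndex(a, dim, n - 1L)
  out <- asgn(out, 1L, first)
  out <- asgn(out, n, last)
  out
}

# run code with a private, seeded RNG stream, restoring global state after
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

atLog <- function(..., verbose = getOption("ActiveTracker.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[ActiveTracker] ", ...)
  invisible(NULL)
}
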