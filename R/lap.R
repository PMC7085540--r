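# Minimum-cost one-to-one assignment (the Hungarian method, shortest
# augmenting path formulation with potentials, O(n^3)). Infeasible pairs
# are marked Inf in the cost matrix; the solver maximises the number of
# feasible matches and, among those, minimises their total cost.

# Square/rectangular Hungarian on a finite cost matrix with nrow <= ncol.
# Returns the column assigned to each row.
hungarianCore <- function(a) {
  n <- nrow(a)
  m <- ncol(a)
  stopifnot(n <= m)
  # potentials: u over rows (index r+1, sentinel row 0 at index 1),
  # v over cols (index j+1... here cols are shifted by 1: col j at j+1,
  # sentinel col at index 1). p[j] = row currently matched to col j-1.
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1L)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      free <- which(!used)
      cur <- a[i0, free - 1L] - u[i0 + 1L] - v[free]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd]] <- j0
      k <- which.min(minv[free])
      delta <- minv[free[k]]
      j1 <- free[k]
      us <- which(used)
      u[p[us] + 1L] <- u[p[us] + 1L] + delta
      v[us] <- v[us] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  rowOf <- p[-1L]            # row matched to each col (0 = none)
  colOf <- integer(n)
  colOf[rowOf[rowOf > 0L]] <- which(rowOf > 0L)
  colOf
}

#' Solve a minimum-cost assignment with infeasible pairs
#'
#' Finds the one-to-one matching between rows and columns of \code{cost}
#' that maximises the number of feasible matches (entries that are finite)
#' and minimises their total cost among such matchings. Among equal-cost
#' optima the lexicographically smallest (row, column) pairing is returned.
#'
#' @param cost numeric matrix; \code{Inf} marks a forbidden pair.
#' @return List with \code{matches} (2-column matrix of row/col indices),
#'   \code{unmatchedRows}, \code{unmatchedCols}, and \code{cost} (total over
#'   matches).
#' @export
solveAssignment <- function(cost) {
  nr <- nrow(cost)
  nc <- ncol(cost)
  empty <- list(matches = matrix(integer(), ncol = 2L,
                                 dimnames = list(NULL, c("row", "col"))),
                unmatchedRows = seq_len(nr), unmatchedCols = seq_len(nc),
                cost = 0)
  if (nr == 0L || nc == 0L || all(!is.finite(cost))) return(empty)
  finite <- cost[is.finite(cost)]
  big <- sum(abs(finite)) + max(abs(finite), 1) + 1
  a <- cost
  a[!is.finite(a)] <- big
  transposed <- nr > nc
  if (transposed) a <- t(a)
  colOf <- hungarianCore(a)
  if (transposed) {
    pairs <- cbind(row = colOf, col = seq_along(colOf))
  } else {
    pairs <- cbind(row = seq_along(colOf), col = colOf)
  }
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L, , drop = FALSE]
  keep <- is.finite(cost[pairs])
  pairs <- pairs[keep, , drop = FALSE]
  pairs <- canonicalizeMatches(cost, pairs)
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  list(matches = pairs,
       unmatchedRows = setdiff(seq_len(nr), pairs[, 1L]),
       unmatchedCols = setdiff(seq_len(nc), pairs[, 2L]),
       cost = sum(cost[pairs]))
}

# Deterministic tie-break: apply cost-neutral pairwise swaps until the
# match list is lexicographically minimal in (row, col).
canonicalizeMatches <- function(cost, pairs) {
  if (nrow(pairs) < 2L) return(pairs)
  repeat {
    swapped <- FALSE
    ord <- order(pairs[, 1L])
    pairs <- pairs[ord, , drop = FALSE]
    for (i in seq_len(nrow(pairs) - 1L)) {
      for (j in seq.int(i + 1L, nrow(pairs))) {
        ri <- pairs[i, 1L]; ci <- pairs[i, 2L]
        rj <- pairs[j, 1L]; cj <- pairs[j, 2L]
        if (cj < ci &&
            is.finite(cost[ri, cj]) && is.finite(cost[rj, ci]) &&
            isTRUE(all.equal(cost[ri, cj] + cost[rj, ci],
                             cost[ri, ci] + cost[rj, cj]))) {
          pairs[i, 2L] <- cj
          pairs[j, 2L] <- ci
          swapped <- TRUE
        }
      }
    }
    if (!swapped) break
  }
  pairs
}
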