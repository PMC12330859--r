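# Hungarian (Kuhn-Munkres) solver for the linear assignment problem, in the
# O(n^3) potentials-and-augmenting-paths form. Cost matrices here are tiny
# (k x k with k <= 7 cluster labels), but the solver is general.

#' Solve a square linear assignment problem (minimization)
#'
#' @param cost n x n numeric cost matrix; entry (i, j) is the cost of
#'   assigning row i to column j.
#' @return integer vector `a` of length n with `a[i]` the column assigned to
#'   row i; attribute \code{"cost"} carries the total cost.
#' @export
solveAssignment <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  # column 0 is a virtual column; R indices are shifted by one
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) a[p[j + 1L]] <- j
  total <- sum(cost[cbind(seq_len(n), a)])
  structure(a, cost = total)
}
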