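# Minimum-cost perfect matching on a square cost matrix via the
# Jonker-Volgenant shortest-augmenting-path algorithm with potentials,
# O(n^3). Returns the column matched to each row. Used for matching
# centroids between clustering runs; tested against the exhaustive
# permutation minimum for small n.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  if (!all(is.finite(cost))) stop("cost matrix must be finite")
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials; index 1 is the virtual column
  p <- integer(n + 1L)     # p[j]: row currently assigned to column j-1 (0 = none)
  way <- integer(n + 1L)
  jreal <- 2:(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- jreal[!used[jreal]]
      cur <- cost[i0, free - 1L] - u[i0] - v[free]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd]] <- j0
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
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
  match_of_row <- integer(n)
  match_of_row[p[jreal]] <- jreal - 1L
  match_of_row
}
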