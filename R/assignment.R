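# Hungarian algorithm (potentials + augmenting paths, O(n^3)) for the
# square linear assignment problem, minimising total cost. Used to align
# cluster labels across partitions by maximum overlap; verified against
# brute-force permutation search in the test suite.
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  n <- nrow(cost)
  if (n == 0L) return(integer())
  u <- numeric(n)
  v <- numeric(n)
  p <- integer(n + 1L)    # p[j+1]: row matched to column j; p[1] scratch
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq(2L, n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0] - v[j - 1L]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          if (j > 1L) v[j - 1L] <- v[j - 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
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
  match_col <- integer(n)
  for (j in seq(2L, n + 1L)) match_col[p[j]] <- j - 1L
  match_col
}
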