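# Linear assignment by the Hungarian method (potentials + shortest
# augmenting path, O(n^3)). No assignment-solver package is part of the
# package's dependency set, and the linking objective is central to the
# tracker, so the solver is implemented here.

# Minimize sum(cost[i, match[i]]) over permutations `match` of a square,
# finite cost matrix. Returns the integer permutation vector.
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  n <- nrow(cost)
  if (n == 0) return(integer(0))
  u <- numeric(n + 1)       # row potentials (u[i] for row i)
  v <- numeric(n + 1)       # column potentials; v[1] is the virtual column 0
  p <- integer(n + 1)       # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0
      red <- cost[i0, ] - u[i0] - v[2:(n + 1)]
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          if (red[j] < minv[j + 1]) {
            minv[j + 1] <- red[j]
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) match[p[j + 1]] <- j
  match
}

# Partial matching between two point sets with per-pair costs and a
# per-unmatched-item penalty `unmatched`. Pairs with non-finite cost are
# forbidden. Minimizes sum(matched costs) + unmatched * (# unmatched items).
# Returns an integer vector over rows: matched column index or NA.
#
# Implemented as assignment on the standard augmented (n+m) square matrix:
# top-left the pair costs, diagonal birth/death blocks at `unmatched`,
# lower-right zero.
match_partial <- function(cost, unmatched) {
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0) return(integer(0))
  if (m == 0) return(rep(NA_integer_, n))
  finite <- is.finite(cost)
  big <- 2 * unmatched * (n + m) + sum(cost[finite]) + 1
  aug <- matrix(big, n + m, m + n)
  aug[seq_len(n), seq_len(m)][!finite] <- big
  aug[seq_len(n), seq_len(m)][finite] <- cost[finite]
  for (i in seq_len(n)) aug[i, m + i] <- unmatched          # row death
  for (j in seq_len(m)) aug[n + j, j] <- unmatched          # column birth
  aug[(n + 1):(n + m), (m + 1):(m + n)] <- 0                # dummy-dummy
  sol <- solve_assignment(aug)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- sol[i]
    if (j <= m && is.finite(cost[i, j])) out[i] <- j
  }
  out
}
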