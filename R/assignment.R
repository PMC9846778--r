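#' Minimum-cost bipartite assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for an n x m cost matrix with
#' n <= m: assigns each row to a distinct column minimising total cost.
#' Shortest-augmenting-path formulation with dual potentials, O(n^2 m).
#'
#' @param cost Numeric cost matrix, `nrow(cost) <= ncol(cost)`.
#' @return Integer vector of length `nrow(cost)`: the column assigned to each
#'   row.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("cost matrix must have nrow <= ncol")
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)    # p[j + 1]: row matched to column j (0 = none; j = 0 virtual)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
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
      }
      for (j in 0:m) {
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
  match <- integer(n)
  for (j in seq_len(m)) {
    if (p[j + 1L] > 0L) match[p[j + 1L]] <- j
  }
  match
}
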