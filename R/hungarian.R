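#' Solve the linear assignment problem (Hungarian method)
#'
#' Finds a permutation \eqn{\sigma} minimising \eqn{\sum_i D[i, \sigma(i)]}
#' for a square cost matrix, using the O(n^3) shortest-augmenting-path
#' formulation with dual potentials (a standard Hungarian-algorithm
#' variant). When several assignments attain the minimum cost, the
#' lexicographically smallest permutation is returned, which makes cluster
#' stitching deterministic.
#'
#' @param d Square numeric cost matrix (no `NA`).
#' @param tol Tolerance used when testing a candidate column for membership
#'   in some optimal assignment during lexicographic tie-breaking.
#' @return List with `assignment` (integer vector, `assignment[i]` is the
#'   column matched to row `i`) and `cost` (the minimal total cost).
#' @examples
#' solve_assignment(matrix(c(1, 3, 2, 0), 2, 2))$assignment  # 1 2
#' @export
solve_assignment <- function(d, tol = 1e-9) {
  stopifnot(is.matrix(d))
  if (nrow(d) != ncol(d)) {
    stop("cost matrix must be square (got ", nrow(d), " x ", ncol(d), ")")
  }
  if (anyNA(d)) stop("cost matrix contains NA")
  n <- nrow(d)
  if (n == 0L) return(list(assignment = integer(0), cost = 0))
  opt <- .lap_cost(d)
  eps <- tol * max(1, max(abs(d)))

  # Fix columns row by row, keeping the partial assignment extendable to an
  # optimal one; yields the lexicographically smallest optimal permutation.
  assignment <- integer(n)
  free_cols <- seq_len(n)
  rows_left <- seq_len(n)
  acc <- 0
  for (i in seq_len(n)) {
    rows_left <- rows_left[rows_left != i]
    for (j in free_cols) {
      rest <- if (length(rows_left)) {
        .lap_cost(d[rows_left, setdiff(free_cols, j), drop = FALSE])
      } else 0
      if (acc + d[i, j] + rest <= opt + eps) {
        assignment[i] <- j
        acc <- acc + d[i, j]
        free_cols <- setdiff(free_cols, j)
        break
      }
    }
  }
  list(assignment = assignment, cost = sum(d[cbind(seq_len(n), assignment)]))
}

# Minimal assignment cost via shortest augmenting paths with potentials.
# Index 0 of the classical formulation is mapped to index n+1 here.
.lap_cost <- function(a) {
  n <- nrow(a)
  if (n == 0L) return(0)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j]: row assigned to column j; p[n+1]: virtual
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- a[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          if (j <= n) v[j] <- v[j] - delta
        } else if (j <= n) {
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
      if (j0 == n + 1L) break
    }
  }
  sum(a[cbind(p[seq_len(n)], seq_len(n))])
}
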