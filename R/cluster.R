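#' Agglomerative average-linkage clustering under the masked distance
#'
#' Starts from singleton clusters and repeatedly merges the pair of
#' clusters with the smallest average-linkage distance until `t` clusters
#' remain. After merging clusters \eqn{C_r} and \eqn{C_s}, the distance of
#' the union to every other cluster \eqn{C_k} is updated as
#' \deqn{d(C_{rs}, C_k) = \frac{|C_r| d(C_r,C_k) + |C_s| d(C_s,C_k)}
#'                             {|C_r| + |C_s|}}
#' which on complete data coincides exactly with recomputing the mean of
#' all cross-pair distances. Under missing data the update is taken as the
#' definition (the masked pairwise mean may differ; see the methods
#' vignette).
#'
#' Ties are broken deterministically: among pairs at the minimum distance,
#' the pair whose (smaller label, larger label) is lexicographically
#' smallest is merged, where a cluster's label is the smallest original row
#' index of its members.
#'
#' @param x Numeric matrix (reads x bins, `NA` missing) of window members.
#'   Ignored when `d` is supplied.
#' @param t Target number of clusters (>= 1).
#' @param d Optional precomputed symmetric distance matrix.
#' @return Integer vector of cluster labels in `1..t`, numbered by the
#'   smallest member row index (cluster 1 contains row 1). If fewer rows
#'   than `t` are supplied, each row is its own cluster (with a warning).
#' @export
agglomerative_cluster <- function(x = NULL, t, d = NULL) {
  if (is.null(d)) d <- masked_distance_matrix(x)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (t < 1) stop("t must be >= 1")
  n <- nrow(d)
  if (n == 0L) return(integer(0))
  if (n < t) {
    warning("fewer reads (", n, ") than clusters (", t, "); returning ",
            n, " singletons")
  }
  if (n <= t) return(seq_len(n))

  size <- rep(1L, n)
  alive <- rep(TRUE, n)
  rep_of <- seq_len(n)           # row index -> representative (min member index)
  diag(d) <- NA_real_
  d[lower.tri(d)] <- NA_real_    # work on the upper triangle only

  for (k in seq_len(n - t)) {
    # argmin over alive pairs; which() scans column-major so the first hit
    # at the minimum is the lexicographically smallest (row, col) pair --
    # but we need (min row) first, so resolve ties explicitly.
    dm <- min(d[alive, alive], na.rm = TRUE)
    hits <- which(d == dm, arr.ind = TRUE)
    hits <- hits[alive[hits[, 1L]] & alive[hits[, 2L]], , drop = FALSE]
    o <- order(hits[, 1L], hits[, 2L])[1L]
    r <- hits[o, 1L]
    s <- hits[o, 2L]

    others <- which(alive)
    others <- others[others != r & others != s]
    if (length(others)) {
      drk <- ifelse(others < r, d[cbind(others, r)], d[cbind(r, others)])
      dsk <- ifelse(others < s, d[cbind(others, s)], d[cbind(s, others)])
      upd <- (size[r] * drk + size[s] * dsk) / (size[r] + size[s])
      lo <- pmin(others, r)
      hi <- pmax(others, r)
      d[cbind(lo, hi)] <- upd
    }
    alive[s] <- FALSE
    size[r] <- size[r] + size[s]
    rep_of[rep_of == s] <- r
  }

  reps <- sort(unique(rep_of))
  match(rep_of, reps)
}

#' Cluster mean methylation profiles
#'
#' The mean profile \eqn{\mu_i} of a cluster is the per-bin mean over the
#' observed (non-missing) entries of its member reads; bins observed by no
#' member stay missing.
#'
#' @param x Member matrix (reads x bins, `NA` missing).
#' @param labels Integer cluster labels, one per row of `x`.
#' @param t Number of profiles to return (default `max(labels)`); labels
#'   absent from `labels` yield all-`NA` rows flagged in the
#'   `"empty_clusters"` attribute.
#' @return A `t` x `ncol(x)` matrix of mean profiles.
#' @export
cluster_means <- function(x, labels, t = max(labels, 0L)) {
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  mu <- matrix(NA_real_, t, ncol(x))
  for (k in seq_len(t)) {
    rows <- which(labels == k)
    if (!length(rows)) next
    sub <- x[rows, , drop = FALSE]
    m <- colMeans(sub, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    mu[k, ] <- m
  }
  attr(mu, "empty_clusters") <- setdiff(seq_len(t), unique(labels))
  mu
}
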