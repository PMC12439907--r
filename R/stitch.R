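#' Build the stitching cost matrix for two adjacent windows
#'
#' Entry (i, j) is the masked distance between mean profile i of window N
#' and mean profile j of window N+1, restricted to the grid bins the two
#' windows share (the only support the window-local profiles have in
#' common). Empty (padded) clusters get distance 1 to everything so that
#' real clusters pair preferentially; a non-empty cluster with no observed
#' overlap bin falls back to the zero-on-disjoint rule with a warning.
#'
#' @param wc_n,wc_n1 Two consecutive window clusterings from
#'   [cluster_windows()].
#' @return A t x t cost matrix.
#' @export
build_stitch_cost <- function(wc_n, wc_n1) {
  shared <- intersect(wc_n$window$bins, wc_n1$window$bins)
  if (!length(shared)) stop("adjacent windows share no bins; cannot stitch")
  t <- nrow(wc_n$mu)
  stopifnot(nrow(wc_n1$mu) == t)
  a <- wc_n$mu[, match(shared, wc_n$window$bins), drop = FALSE]
  b <- wc_n1$mu[, match(shared, wc_n1$window$bins), drop = FALSE]
  d <- matrix(0, t, t)
  warned <- FALSE
  for (i in seq_len(t)) {
    for (j in seq_len(t)) {
      if (i %in% wc_n$empty_clusters || j %in% wc_n1$empty_clusters) {
        d[i, j] <- 1
      } else {
        if (!warned && all(is.na(a[i, ]) | is.na(b[j, ]))) {
          warning("cluster profile unobserved on the window overlap; ",
                  "masked distance falls back to 0")
          warned <- TRUE
        }
        d[i, j] <- masked_distance(a[i, ], b[j, ])
      }
    }
  }
  d
}

#' Stitch window clusterings into locus-spanning cluster series
#'
#' For every pair of adjacent windows the t clusters are matched one-to-one
#' by solving the assignment problem on the masked distances between their
#' mean profiles over the shared bins ([solve_assignment()]); chaining the
#' matchings left to right yields t series, each a chain of one cluster
#' per window. Series are numbered by their cluster id in the first
#' window. The region-level profile of a series averages its per-window
#' mean profiles bin-wise (unweighted over the windows observing the bin).
#'
#' @param wcs List of window clusterings from [cluster_windows()], left to
#'   right.
#' @param n_bins Total number of grid bins (for the region profile).
#' @return A `cluster_series` object: list with `chain` (M x t matrix of
#'   cluster ids; column s is series s), `profile` (t x n_bins matrix),
#'   `costs` (per-boundary assignment costs) and `assignments` (the
#'   per-boundary permutations, for diagnostics).
#' @export
stitch_windows <- function(wcs, n_bins) {
  stopifnot(length(wcs) >= 1L)
  t <- nrow(wcs[[1L]]$mu)
  m <- length(wcs)
  chain <- matrix(NA_integer_, m, t)
  chain[1L, ] <- seq_len(t)
  perms <- vector("list", max(0L, m - 1L))
  costs <- numeric(max(0L, m - 1L))
  if (m > 1L) {
    for (w in seq_len(m - 1L)) {
      d <- build_stitch_cost(wcs[[w]], wcs[[w + 1L]])
      sol <- solve_assignment(d)
      perms[[w]] <- sol$assignment
      costs[w] <- sol$cost
      chain[w + 1L, ] <- sol$assignment[chain[w, ]]
    }
  }

  num <- matrix(0, t, n_bins)
  den <- matrix(0L, t, n_bins)
  for (w in seq_len(m)) {
    bins <- wcs[[w]]$window$bins
    mu <- wcs[[w]]$mu
    for (s in seq_len(t)) {
      v <- mu[chain[w, s], ]
      obs <- !is.na(v)
      num[s, bins[obs]] <- num[s, bins[obs]] + v[obs]
      den[s, bins[obs]] <- den[s, bins[obs]] + 1L
    }
  }
  profile <- num / den
  profile[den == 0L] <- NA_real_

  structure(list(chain = chain, profile = profile, costs = costs,
                 assignments = perms, n_windows = m, t = t),
            class = "cluster_series")
}

#' @export
print.cluster_series <- function(x, ...) {
  cat(sprintf("<cluster_series: %d series stitched across %d windows>\n",
              x$t, x$n_windows))
  invisible(x)
}
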