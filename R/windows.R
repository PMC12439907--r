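#' Define overlapping clustering windows over valid bins
#'
#' A *valid bin* is a bin observed by at least one read. Valid bins are
#' enumerated left to right and tiled with windows of `window_size` valid
#' bins advancing by `window_size - overlap`; the final window is
#' right-anchored on the last valid bin so that it shares at least
#' `overlap` bins with its predecessor. With fewer than `window_size`
#' valid bins a single truncated window is returned with a warning.
#'
#' @param binned A `binned_reads` object.
#' @param window_size Number of valid bins per window (default 60).
#' @param overlap Minimum number of shared valid bins between consecutive
#'   windows (default 20).
#' @return List of windows; each has `index`, `bins` (grid bin indices)
#'   and `valid_range` (positions in the valid-bin enumeration).
#' @export
define_windows <- function(binned, window_size = 60L, overlap = 20L) {
  stopifnot(inherits(binned, "binned_reads"),
            window_size >= 2, overlap >= 1, overlap < window_size)
  valid <- which(colSums(!is.na(binned$values)) > 0L)
  nv <- length(valid)
  if (nv == 0L) stop("no valid bins: no read carries methylation data")
  if (nv < window_size) {
    warning("only ", nv, " valid bins (< window_size = ", window_size,
            "); using a single truncated window")
    return(list(list(index = 1L, bins = valid, valid_range = c(1L, nv))))
  }
  stride <- window_size - overlap
  starts <- seq(1L, nv - window_size + 1L, by = stride)
  if (starts[length(starts)] + window_size - 1L < nv) {
    starts <- c(starts, nv - window_size + 1L)
  }
  lapply(seq_along(starts), function(w) {
    rng <- c(starts[w], starts[w] + window_size - 1L)
    list(index = w, bins = valid[rng[1L]:rng[2L]], valid_range = rng)
  })
}

#' Cluster the reads of every window
#'
#' Within each window, reads with at least `min_read_valid_bins` observed
#' bins are clustered into `t` groups by [agglomerative_cluster()] under
#' the masked distance, and per-cluster mean profiles are computed over
#' the window's bins. Windows with fewer members than `t` are padded with
#' empty clusters (all-`NA` profiles) so every window exposes exactly `t`
#' clusters to the stitching step.
#'
#' @param binned A `binned_reads` object (extremes already removed).
#' @param windows Output of [define_windows()].
#' @param t Number of clusters per window.
#' @param min_read_valid_bins Minimum observed bins inside the window for
#'   a read to participate (default 30).
#' @return List of window clusterings: `window`, `member_rows` (row
#'   indices into `binned$values`), `labels`, `mu` (t x bins matrix) and
#'   `empty_clusters`.
#' @export
cluster_windows <- function(binned, windows, t, min_read_valid_bins = 30L) {
  stopifnot(inherits(binned, "binned_reads"), t >= 1)
  lapply(windows, function(win) {
    sub <- binned$values[, win$bins, drop = FALSE]
    members <- which(rowSums(!is.na(sub)) >= min_read_valid_bins)
    x <- sub[members, , drop = FALSE]
    labels <- if (length(members)) {
      suppressWarnings(agglomerative_cluster(x, t))
    } else {
      integer(0)
    }
    mu <- cluster_means(x, labels, t = t)
    list(window = win, member_rows = members, labels = labels, mu = mu,
         empty_clusters = attr(mu, "empty_clusters"))
  })
}
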