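#' Masked Hamming distance between two methylation profiles
#'
#' The distance is the mean absolute difference over positions observed in
#' *both* vectors (missing entries are `NA`). When the two vectors share no
#' observed position the distance is defined as 0, i.e. non-overlapping
#' profiles are treated as indistinguishable rather than maximally distant;
#' set `disjoint_value = 1` to invert that convention.
#'
#' On binary profiles this reduces to the Hamming fraction; on fractional
#' bin-level profiles it generalises to a mean absolute difference.
#'
#' @param u,v Numeric vectors of equal length; `NA` marks missing entries.
#' @param disjoint_value Value returned when no position is co-observed
#'   (default 0).
#' @return A scalar in `[0, 1]`.
#' @examples
#' masked_distance(c(1, 0, NA), c(0, 0, 1))  # 0.5
#' @export
masked_distance <- function(u, v, disjoint_value = 0) {
  if (length(u) != length(v)) {
    stop("masked_distance: vectors differ in length (",
         length(u), " vs ", length(v), ")")
  }
  m <- !is.na(u) & !is.na(v)
  if (!any(m)) return(disjoint_value)
  mean(abs(u[m] - v[m]))
}

#' Pairwise masked-distance matrix
#'
#' @param x Numeric matrix, rows = reads, columns = bins, `NA` = missing.
#' @param disjoint_value See [masked_distance()].
#' @return A symmetric `nrow(x)` x `nrow(x)` matrix with zero diagonal.
#' @export
masked_distance_matrix <- function(x, disjoint_value = 0) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  d <- matrix(0, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    idx <- (i + 1L):n
    ad <- abs(x[idx, , drop = FALSE] -
                matrix(x[i, ], length(idx), ncol(x), byrow = TRUE))
    di <- rowMeans(ad, na.rm = TRUE)
    di[is.nan(di)] <- disjoint_value
    d[i, idx] <- di
    d[idx, i] <- di
  }
  d
}

#' Masked distances from one profile to each row of a matrix
#'
#' Rows sharing no observed bin with `u` get `NA` (callers decide how to
#' treat zero overlap: the global assignment step marks such reads
#' unassigned instead of applying the zero-on-disjoint rule, which would
#' make the choice of series arbitrary).
#'
#' @param u Numeric vector with `NA` missing entries.
#' @param profiles Matrix with `length(u)` columns.
#' @return List with `distance` and `n_shared` (co-observed bins per row).
#' @export
masked_distance_to_profiles <- function(u, profiles) {
  stopifnot(is.matrix(profiles), ncol(profiles) == length(u))
  ad <- abs(profiles - matrix(u, nrow(profiles), length(u), byrow = TRUE))
  n_shared <- rowSums(!is.na(ad))
  d <- rowMeans(ad, na.rm = TRUE)
  d[n_shared == 0L] <- NA_real_
  list(distance = d, n_shared = n_shared)
}
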