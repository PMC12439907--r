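#' Filter low-quality / uninformative reads
#'
#' Drops reads whose reference span is below `min_span` or that carry fewer
#' than `min_gpc` GpC calls, the two read-quality thresholds applied before
#' binning.
#'
#' @param calls Call table from [read_methyl_calls()].
#' @param min_span Minimum reference span in bp (default 10).
#' @param min_gpc Minimum number of GpC calls (default 10).
#' @return List with `calls` (retained rows) and `log`, a `data.table` of
#'   dropped reads with the reason (`short_span` / `few_gpc`).
#' @export
filter_reads <- function(calls, min_span = 10, min_gpc = 10) {
  stats <- calls[, .(span = max(position) - min(position) + 1, n_gpc = .N),
                 by = read_id]
  stats[, reason := fifelse(span < min_span, "short_span",
                            fifelse(n_gpc < min_gpc, "few_gpc", NA_character_))]
  dropped <- stats[!is.na(reason)]
  kept <- calls[!read_id %in% dropped$read_id]
  list(calls = kept, log = dropped[, .(read_id, span, n_gpc, reason)])
}

#' Bin per-site calls into a fixed-width bin matrix
#'
#' Each entry is the fraction of methylated GpC calls of that read falling
#' in that bin; bins inside the read's span with no call, and all bins
#' outside the span, are missing (`NA`).
#'
#' A read's first and last covered bins are usually truncated by the read
#' boundary, so their fraction is estimated from a censored subset of the
#' bin's GpC sites and is biased at nucleosome edges; with
#' `mask_boundary = TRUE` (default) those two bins are treated as missing,
#' consistent with the masked-distance philosophy of discarding unreliable
#' entries rather than letting them distort cluster means.
#'
#' @param calls Filtered call table.
#' @param grid A [bin_grid()] covering every call position.
#' @param mask_boundary Mask each read's first and last covered bin
#'   (default `TRUE`).
#' @return A `binned_reads` object: list with `values` (reads x bins
#'   matrix), `read_id`, `grid`, `n_gpc`, `n_valid_bins` and `span`
#'   (first/last covered bin per read).
#' @export
bin_reads <- function(calls, grid, mask_boundary = TRUE) {
  stopifnot(inherits(grid, "bin_grid"))
  calls <- data.table::copy(calls)
  calls[, bin := bin_index(grid, position)]
  if (anyNA(calls$bin)) {
    stop("call positions outside the bin grid (",
         sum(is.na(calls$bin)), " calls)")
  }
  ids <- sort(unique(calls$read_id))
  agg <- calls[, .(frac = mean(call), n = .N),
               by = .(read_id, bin)]
  values <- matrix(NA_real_, length(ids), grid$n_bins)
  values[cbind(match(agg$read_id, ids), agg$bin)] <- agg$frac
  n_gpc <- calls[, .N, by = read_id][match(ids, read_id), N]
  span <- agg[, .(first = min(bin), last = max(bin)), by = read_id]
  span <- span[match(ids, read_id)]
  if (mask_boundary) {
    rows <- seq_along(ids)
    values[cbind(rows, span$first)] <- NA_real_
    values[cbind(rows, span$last)] <- NA_real_
  }
  structure(list(values = values, read_id = ids, grid = grid,
                 n_gpc = n_gpc,
                 n_valid_bins = rowSums(!is.na(values)),
                 span = span[, .(first, last)]),
            class = "binned_reads")
}

#' @export
print.binned_reads <- function(x, ...) {
  cat(sprintf("<binned_reads: %d reads x %d bins (%d bp), %.1f%% observed>\n",
              nrow(x$values), ncol(x$values), x$grid$bin_width,
              100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Smooth binned profiles with a masked rolling mean
#'
#' Each observed entry is replaced by the mean of the observed entries
#' within `half_window` bins on either side (same read). Missing entries
#' stay missing and observed entries never become missing, so smoothing
#' commutes with the missingness mask.
#'
#' @param binned A `binned_reads` object.
#' @param half_window Non-negative integer; 0 is the identity.
#' @return A `binned_reads` object with smoothed `values`.
#' @export
smooth_bins <- function(binned, half_window = 1L) {
  stopifnot(inherits(binned, "binned_reads"), half_window >= 0)
  if (half_window == 0L) return(binned)
  x <- binned$values
  obs <- !is.na(x)
  x0 <- ifelse(obs, x, 0)
  num <- x0
  den <- obs * 1
  for (k in seq_len(half_window)) {
    nb <- ncol(x)
    shift_l <- function(m) cbind(m[, -seq_len(k), drop = FALSE],
                                 matrix(0, nrow(m), k))
    shift_r <- function(m) cbind(matrix(0, nrow(m), k),
                                 m[, seq_len(nb - k), drop = FALSE])
    num <- num + shift_l(x0) + shift_r(x0)
    den <- den + shift_l(obs * 1) + shift_r(obs * 1)
  }
  sm <- num / den
  sm[!obs] <- NA_real_
  binned$values <- sm
  binned
}

#' Pre-assign fully methylated / fully unmethylated molecules
#'
#' Reads whose mean observed methylation is `>= theta` are labelled
#' `FULLY_METH`, those `<= 1 - theta` `FULLY_UNMETH`; both carry little
#' footprint information and are ambiguous for stitching, so they are set
#' aside before clustering.
#'
#' @param binned A `binned_reads` object.
#' @param theta Threshold in (0.5, 1]; default 0.95.
#' @return List with `binned` (extremes removed), `labels` (named
#'   character vector read_id -> label) for the extremes.
#' @export
preassign_extremes <- function(binned, theta = 0.95) {
  stopifnot(inherits(binned, "binned_reads"), theta > 0.5, theta <= 1)
  mm <- rowMeans(binned$values, na.rm = TRUE)
  lab <- ifelse(mm >= theta, "FULLY_METH",
                ifelse(mm <= 1 - theta, "FULLY_UNMETH", NA_character_))
  extreme <- !is.na(lab)
  labels <- stats::setNames(lab[extreme], binned$read_id[extreme])
  keep <- which(!extreme)
  binned$values <- binned$values[keep, , drop = FALSE]
  binned$read_id <- binned$read_id[keep]
  binned$n_gpc <- binned$n_gpc[keep]
  binned$n_valid_bins <- binned$n_valid_bins[keep]
  binned$span <- binned$span[keep]
  list(binned = binned, labels = labels)
}
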