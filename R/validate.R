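#' Leave-one-out accuracy of a long read
#'
#' Holds out one long read, phases the locus from the remaining molecules
#' (the grid, valid bins, windows and filters are all recomputed without
#' the held-out read, so it cannot leak into any stage), bins the held-out
#' read on the hold-out grid, and scores
#' \deqn{A(r_i) = 1 - \min_j d_H(r_i, c_j)}
#' where the minimum runs over the stitched series profiles and \eqn{d_H}
#' is the masked distance.
#'
#' @param calls Full call table for the locus.
#' @param region A [region_spec()].
#' @param long_read_id Identifier of the read to hold out.
#' @param t Number of cluster series.
#' @param params Optional parameter overrides, see [phase_params()].
#' @param min_long_length Minimum reference span in bp for a read to
#'   qualify as long (default 50000).
#' @return List (an accuracy record) with `read_id`, `read_length`,
#'   `best_series` (0-based), `accuracy` and `n_shared_bins`. If the
#'   held-out read shares no bin with any series, `accuracy` is `NA` and
#'   `error` explains why.
#' @export
evaluate_long_read <- function(calls, region, long_read_id, t,
                               params = list(), min_long_length = 50000) {
  rc <- calls[calls$read_id == long_read_id]
  if (nrow(rc) == 0L) stop("read not found: ", long_read_id)
  read_length <- max(rc$position) - min(rc$position) + 1
  if (read_length < min_long_length) {
    stop("read ", long_read_id, " spans ", read_length,
         " bp (< min_long_length = ", min_long_length, ")")
  }
  rest <- calls[calls$read_id != long_read_id]
  bundle <- phase_reads(rest, region, t, params)

  grid <- bundle$grid
  rc <- rc[rc$position >= grid$start[1] &
             rc$position < grid$end[grid$n_bins]]
  held <- bin_reads(rc, grid)
  if (bundle$params$smooth_half_window > 0L) {
    held <- smooth_bins(held, bundle$params$smooth_half_window)
  }
  dd <- masked_distance_to_profiles(held$values[1L, ],
                                    bundle$series$profile)
  if (all(is.na(dd$distance))) {
    return(list(read_id = long_read_id, read_length = read_length,
                best_series = NA_integer_, accuracy = NA_real_,
                n_shared_bins = 0L,
                error = "no bin shared with any series"))
  }
  k <- which.min(dd$distance)
  list(read_id = long_read_id, read_length = read_length,
       best_series = k - 1L, accuracy = 1 - dd$distance[k],
       n_shared_bins = dd$n_shared[k], error = NA_character_)
}

#' Leave-one-out accuracy over many loci
#'
#' Evaluates [evaluate_long_read()] for every qualifying long read of every
#' locus and averages the accuracies into the overall clustering accuracy.
#' Loci whose evaluation fails (e.g. insufficient residual coverage) are
#' reported as skipped rather than aborting the sweep.
#'
#' @param loci List of loci; each element is a list with `calls`,
#'   `region`, `t`, optional `params`, and optional `long_read_ids`
#'   (default: every read spanning at least `min_long_length`), plus an
#'   optional `locus_id`.
#' @param min_long_length Minimum long-read span in bp (default 50000).
#' @return An `accuracy_report`: list with `records` (`data.table`:
#'   locus, read_id, read_length, best_series, accuracy), `overall`
#'   (mean accuracy) and `skipped` (`data.table` of locus/read/reason).
#' @export
evaluate_many <- function(loci, min_long_length = 50000) {
  stopifnot(length(loci) >= 1L)
  recs <- list()
  skipped <- list()
  for (i in seq_along(loci)) {
    L <- loci[[i]]
    locus_id <- if (!is.null(L$locus_id)) L$locus_id else paste0("locus", i)
    ids <- L$long_read_ids
    if (is.null(ids)) {
      spans <- L$calls[, .(span = max(position) - min(position) + 1),
                       by = read_id]
      ids <- spans[span >= min_long_length, read_id]
    }
    if (!length(ids)) {
      skipped[[length(skipped) + 1L]] <- data.table::data.table(
        locus = locus_id, read_id = NA_character_,
        reason = "no qualifying long read")
      next
    }
    for (id in ids) {
      rec <- tryCatch(
        evaluate_long_read(L$calls, L$region, id, L$t,
                           params = if (is.null(L$params)) list() else L$params,
                           min_long_length = min_long_length),
        error = function(e) conditionMessage(e))
      if (is.character(rec) || !is.na(rec$error)) {
        skipped[[length(skipped) + 1L]] <- data.table::data.table(
          locus = locus_id, read_id = id,
          reason = if (is.character(rec)) rec else rec$error)
      } else {
        recs[[length(recs) + 1L]] <- data.table::data.table(
          locus = locus_id, read_id = rec$read_id,
          read_length = rec$read_length, best_series = rec$best_series,
          accuracy = rec$accuracy)
      }
    }
  }
  records <- if (length(recs)) data.table::rbindlist(recs) else
    data.table::data.table(locus = character(), read_id = character(),
                           read_length = numeric(),
                           best_series = integer(), accuracy = numeric())
  structure(list(records = records,
                 overall = if (nrow(records)) mean(records$accuracy) else NA_real_,
                 skipped = if (length(skipped)) data.table::rbindlist(skipped) else
                   data.table::data.table(locus = character(),
                                          read_id = character(),
                                          reason = character())),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report: %d long reads, overall accuracy %.3f (%d skipped)>\n",
              nrow(x$records), x$overall, nrow(x$skipped)))
  invisible(x)
}
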