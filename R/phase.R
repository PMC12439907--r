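#' Assign every read to its most similar stitched cluster series
#'
#' Computes the masked distance between each read's full binned profile
#' and each series' region-level profile, and assigns the argmin (ties go
#' to the lowest series id). A read sharing no observed bin with any
#' series is labelled `UNASSIGNED` rather than placed arbitrarily by the
#' zero-on-disjoint distance rule.
#'
#' @param binned A `binned_reads` object (clustering-eligible reads).
#' @param profile t x n_bins matrix of series profiles.
#' @return `data.table` with `read_id`, `series` (1-based id or `NA`),
#'   `distance`, `n_shared_bins`.
#' @export
assign_global <- function(binned, profile) {
  stopifnot(inherits(binned, "binned_reads"), is.matrix(profile))
  if (nrow(profile) == 0L) stop("no cluster series to assign to")
  n <- nrow(binned$values)
  series <- integer(n)
  dist <- numeric(n)
  shared <- integer(n)
  for (r in seq_len(n)) {
    dd <- masked_distance_to_profiles(binned$values[r, ], profile)
    if (all(is.na(dd$distance))) {
      series[r] <- NA_integer_
      dist[r] <- NA_real_
      shared[r] <- 0L
    } else {
      k <- which.min(dd$distance)  # first minimum = lowest series id
      series[r] <- k
      dist[r] <- dd$distance[k]
      shared[r] <- dd$n_shared[k]
    }
  }
  data.table::data.table(read_id = binned$read_id, series = series,
                         distance = dist, n_shared_bins = shared)
}

#' Summarise final phased series
#'
#' Recomputes each series' member count, proportion of assigned reads,
#' mean profile over the final membership and per-bin occupancy depth.
#'
#' @param binned A `binned_reads` object.
#' @param assignments Output of [assign_global()].
#' @param t Number of series.
#' @return List with `n_reads`, `proportion`, `profile` (t x bins),
#'   `depth` (t x bins integer matrix).
#' @export
series_summary <- function(binned, assignments, t) {
  stopifnot(nrow(assignments) == nrow(binned$values))
  n_bins <- ncol(binned$values)
  profile <- matrix(NA_real_, t, n_bins)
  depth <- matrix(0L, t, n_bins)
  n_reads <- integer(t)
  for (k in seq_len(t)) {
    rows <- which(assignments$series == k)
    n_reads[k] <- length(rows)
    if (!length(rows)) next
    sub <- binned$values[rows, , drop = FALSE]
    obs <- !is.na(sub)
    depth[k, ] <- colSums(obs)
    m <- colMeans(sub, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    profile[k, ] <- m
  }
  n_assigned <- sum(n_reads)
  list(n_reads = n_reads,
       proportion = if (n_assigned) n_reads / n_assigned else rep(NA_real_, t),
       profile = profile, depth = depth)
}

#' Iteratively refine the global assignment (optional)
#'
#' Alternates recomputing series profiles from the current membership with
#' reassigning every read to its closest profile, until the assignment is
#' stable or `max_iter` passes have run. `max_iter = 0` returns the input
#' unchanged; the default pipeline performs a single global reassignment
#' and does not iterate.
#'
#' @param binned A `binned_reads` object.
#' @param assignments Output of [assign_global()].
#' @param t Number of series.
#' @param max_iter Maximum refinement passes (default 1).
#' @return List with `assignments`, `summary` (final [series_summary()])
#'   and `iterations` actually run.
#' @export
reassign_iterate <- function(binned, assignments, t, max_iter = 1L) {
  stopifnot(max_iter >= 0)
  it <- 0L
  while (it < max_iter) {
    summ <- series_summary(binned, assignments, t)
    new_asn <- assign_global(binned, summ$profile)
    it <- it + 1L
    if (identical(new_asn$series, assignments$series)) {
      assignments <- new_asn
      break
    }
    assignments <- new_asn
  }
  list(assignments = assignments,
       summary = series_summary(binned, assignments, t),
       iterations = it)
}

#' Total within-series masked distance of an assignment
#'
#' @param binned A `binned_reads` object.
#' @param assignments Assignment table.
#' @param profile Series profiles the distances are measured against; by
#'   default recomputed from the assignment.
#' @param t Number of series.
#' @return Scalar sum of masked distances of assigned reads to their
#'   series profile.
#' @export
total_within_distance <- function(binned, assignments, t,
                                  profile = NULL) {
  if (is.null(profile)) {
    profile <- series_summary(binned, assignments, t)$profile
  }
  tot <- 0
  for (r in which(!is.na(assignments$series))) {
    tot <- tot + masked_distance(binned$values[r, ],
                                 profile[assignments$series[r], ])
  }
  tot
}

#' Phase a locus end to end
#'
#' Runs the full cluster-based phasing pipeline on a per-read call table:
#' read filtering, 50-bp binning, pre-assignment of fully methylated /
#' unmethylated molecules, per-window agglomerative clustering under the
#' masked distance, Hungarian stitching of clusters across overlapping
#' windows, and a final global reassignment of every molecule to its
#' best-matched stitched series.
#'
#' @param calls Call table from [read_methyl_calls()] (or
#'   [simulate_locus()]).
#' @param region A [region_spec()].
#' @param t Number of cluster series.
#' @param params Optional list overriding [phase_params()] defaults.
#' @return A `phasing_bundle`: list with `assignments` (one row per input
#'   read: `read_id`, `label` in `{0..t-1, FULLY_METH, FULLY_UNMETH,
#'   UNASSIGNED, FILTERED}`, `distance`, `n_shared_bins`), `series`
#'   (summary with profiles/proportions), `grid`, `windows`, `stitch`,
#'   `counts` (per-stage read counts) and `params`.
#' @export
phase_reads <- function(calls, region, t, params = list()) {
  p <- phase_params(params)
  n_input_reads <- length(unique(calls$read_id))

  flt <- filter_reads(calls, min_span = p$min_read_span, min_gpc = p$min_gpc)
  if (nrow(flt$calls) == 0L) stop("no reads left after filtering")

  grid <- bin_grid(region,
                   first_pos = min(flt$calls$position),
                   last_pos = max(flt$calls$position),
                   bin_width = p$bin_width)
  binned <- bin_reads(flt$calls, grid)
  if (p$smooth_half_window > 0L) {
    binned <- smooth_bins(binned, p$smooth_half_window)
  }

  pre <- preassign_extremes(binned, theta = p$extreme_theta)
  binned_cl <- pre$binned
  if (nrow(binned_cl$values) == 0L) stop("no reads left for clustering")

  windows <- define_windows(binned_cl, window_size = p$window_size,
                            overlap = p$window_overlap)
  wcs <- cluster_windows(binned_cl, windows, t,
                         min_read_valid_bins = p$min_read_valid_bins)
  stitched <- stitch_windows(wcs, n_bins = grid$n_bins)

  asn <- assign_global(binned_cl, stitched$profile)
  if (p$max_reassign_iter > 0L) {
    ref <- reassign_iterate(binned_cl, asn, t,
                            max_iter = p$max_reassign_iter)
    asn <- ref$assignments
  }
  summ <- series_summary(binned_cl, asn, t)

  # assemble one labelled row per input read
  lab_tab <- data.table::data.table(
    read_id = asn$read_id,
    label = ifelse(is.na(asn$series), "UNASSIGNED",
                   as.character(asn$series - 1L)),
    distance = asn$distance,
    n_shared_bins = asn$n_shared_bins)
  if (length(pre$labels)) {
    lab_tab <- rbind(lab_tab, data.table::data.table(
      read_id = names(pre$labels), label = unname(pre$labels),
      distance = NA_real_, n_shared_bins = NA_integer_))
  }
  if (nrow(flt$log)) {
    lab_tab <- rbind(lab_tab, data.table::data.table(
      read_id = flt$log$read_id, label = "FILTERED",
      distance = NA_real_, n_shared_bins = NA_integer_))
  }
  data.table::setorder(lab_tab, read_id)

  counts <- list(
    n_input = n_input_reads,
    n_filtered_out = nrow(flt$log),
    n_fully_meth = sum(pre$labels == "FULLY_METH"),
    n_fully_unmeth = sum(pre$labels == "FULLY_UNMETH"),
    n_clustering = nrow(binned_cl$values),
    n_assigned = sum(!is.na(asn$series)),
    n_unassigned = sum(is.na(asn$series)),
    n_windows = length(windows))

  structure(list(assignments = lab_tab, series = summ, grid = grid,
                 windows = windows, window_clusterings = wcs,
                 stitch = stitched, binned = binned_cl,
                 preassigned = pre$labels, filter_log = flt$log,
                 counts = counts, params = p, t = t),
            class = "phasing_bundle")
}

#' @export
print.phasing_bundle <- function(x, ...) {
  with(x$counts, cat(sprintf(
    paste0("<phasing_bundle: %d reads -> %d series over %d windows\n",
           "  filtered %d, fully meth %d, fully unmeth %d, ",
           "assigned %d, unassigned %d>\n"),
    n_input, x$t, n_windows, n_filtered_out, n_fully_meth, n_fully_unmeth,
    n_assigned, n_unassigned)))
  invisible(x)
}

#' Default phasing parameters
#'
#' Defaults follow the published pipeline settings: 50-bp bins, windows of
#' 60 valid bins with 20 overlapping bins, read filters of 10 bp span /
#' 10 GpCs / 30 valid bins per window. Smoothing (masked rolling mean) and
#' iterative reassignment are off by default; the extremes threshold
#' `extreme_theta` and the single global reassignment are package choices
#' documented in the methods vignette.
#'
#' @param override Named list of values to override.
#' @return Named list of parameters.
#' @export
phase_params <- function(override = list()) {
  p <- list(
    bin_width = 50L,
    min_read_span = 10,
    min_gpc = 10L,
    smooth_half_window = 0L,
    extreme_theta = 0.95,
    window_size = 60L,
    window_overlap = 20L,
    min_read_valid_bins = 30L,
    max_reassign_iter = 0L,
    min_confidence = 0,
    seed = NA_integer_)
  unknown <- setdiff(names(override), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(override)] <- override
  p
}
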