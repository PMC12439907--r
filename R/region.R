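#' Define a genomic region
#'
#' Coordinates are 0-based half-open throughout the package: a region
#' `[start, end)` contains positions `start, ..., end - 1`.
#'
#' @param contig Contig/chromosome name.
#' @param start 0-based start coordinate (inclusive).
#' @param end End coordinate (exclusive), must satisfy `end > start`.
#' @return A `region_spec` object.
#' @examples
#' region_spec("chr3", 34000000, 34050000)
#' @export
region_spec <- function(contig, start, end) {
  stopifnot(is.character(contig), length(contig) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end <= start) {
    stop("region must satisfy 0 <= start < end")
  }
  structure(list(contig = contig, start = start, end = end),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region %s:%d-%d (0-based half-open, %d bp)>\n",
              x$contig, as.integer(x$start), as.integer(x$end),
              as.integer(x$end - x$start)))
  invisible(x)
}

#' Build a fixed-width bin grid over a region
#'
#' Bins are anchored at the first covered position (typically the leftmost
#' read start, clipped to the region) and tile rightwards in `bin_width`
#' steps until the last covered position; the final bin may be ragged
#' (shorter than `bin_width`).
#'
#' @param region A [region_spec()].
#' @param first_pos,last_pos First and last (inclusive) covered reference
#'   positions; clipped to the region. Defaults to the whole region.
#' @param bin_width Bin width in bp (default 50).
#' @return A `bin_grid` with elements `region`, `bin_width`, `start`
#'   (vector of bin starts) and `end` (vector of bin ends, half-open).
#' @export
bin_grid <- function(region, first_pos = region$start,
                     last_pos = region$end - 1, bin_width = 50L) {
  stopifnot(inherits(region, "region_spec"), bin_width >= 1)
  first_pos <- max(region$start, first_pos)
  last_pos <- min(region$end - 1, last_pos)
  if (last_pos < first_pos) stop("empty grid: no covered positions in region")
  if (region$end - region$start < bin_width) {
    stop("region shorter than one bin width")
  }
  starts <- seq(first_pos, last_pos, by = bin_width)
  ends <- pmin(starts + bin_width, region$end)
  structure(list(region = region, bin_width = as.integer(bin_width),
                 start = starts, end = ends, n_bins = length(starts)),
            class = "bin_grid")
}

#' Map reference positions to bin indices
#'
#' @param grid A [bin_grid()].
#' @param positions 0-based reference positions.
#' @return 1-based bin indices; `NA` for positions outside the grid.
#' @export
bin_index <- function(grid, positions) {
  stopifnot(inherits(grid, "bin_grid"))
  idx <- floor((positions - grid$start[1]) / grid$bin_width) + 1
  idx[positions < grid$start[1] | positions >= grid$end[grid$n_bins]] <- NA
  as.integer(idx)
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid %s: %d bins of %d bp over [%d, %d)>\n",
              x$region$contig, x$n_bins, x$bin_width,
              as.integer(x$start[1]), as.integer(x$end[x$n_bins])))
  invisible(x)
}
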