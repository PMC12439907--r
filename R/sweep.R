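#' Sweep the number of cluster series (extension)
#'
#' The published pipeline takes the number of clusters `t` as a user
#' parameter. This helper — an extension, not part of the core method —
#' runs the full phasing pipeline for each candidate `t` and reports a
#' profile-based mean silhouette under the masked distance: for each
#' assigned read, `a` is its distance to its own series profile and `b`
#' the smallest distance to any other series profile, contributing
#' `(b - a) / max(a, b)`.
#'
#' @param calls Call table.
#' @param region A [region_spec()].
#' @param t_range Integer vector of candidate `t` values (each >= 2).
#' @param params Optional parameter overrides, see [phase_params()].
#' @return `data.table` with `t`, `mean_silhouette`, `n_assigned`.
#' @export
sweep_t <- function(calls, region, t_range, params = list()) {
  stopifnot(all(t_range >= 2))
  res <- lapply(t_range, function(t) {
    bundle <- phase_reads(calls, region, t, params)
    asn <- bundle$assignments[grepl("^[0-9]+$", label)]
    sil <- vapply(seq_len(nrow(asn)), function(i) {
      row <- match(asn$read_id[i], bundle$binned$read_id)
      dd <- masked_distance_to_profiles(bundle$binned$values[row, ],
                                        bundle$series$profile)$distance
      own <- as.integer(asn$label[i]) + 1L
      a <- dd[own]
      b <- min(dd[-own], na.rm = TRUE)
      if (!is.finite(a) || !is.finite(b) || max(a, b) == 0) return(NA_real_)
      (b - a) / max(a, b)
    }, numeric(1))
    data.table::data.table(t = t, mean_silhouette = mean(sil, na.rm = TRUE),
                           n_assigned = nrow(asn))
  })
  data.table::rbindlist(res)
}
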