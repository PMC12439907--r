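library(data.table)

# Build a binned_reads object directly from a values matrix, bypassing the
# call-level representation, for unit tests of downstream stages.
make_binned <- function(values, bin_width = 50L, contig = "chrT",
                        read_id = NULL) {
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(nrow(values)))
  region <- region_spec(contig, 0, ncol(values) * bin_width)
  grid <- bin_grid(region, bin_width = bin_width)
  first <- apply(values, 1, function(v) {
    w <- which(!is.na(v))
    if (length(w)) min(w) else NA_integer_
  })
  last <- apply(values, 1, function(v) {
    w <- which(!is.na(v))
    if (length(w)) max(w) else NA_integer_
  })
  structure(list(values = values, read_id = read_id, grid = grid,
                 n_gpc = rowSums(!is.na(values)),
                 n_valid_bins = rowSums(!is.na(values)),
                 span = data.table::data.table(first = first, last = last)),
            class = "binned_reads")
}

# A small simulated world that exercises every stage (multiple windows,
# fragmented reads) but runs in ~1 s.
small_sim <- function(seed = 7, ...) {
  cfg <- sim_config(locus_length = 12000L, coverage = 40,
                    read_length_median = 2500, n_long_reads = 1L,
                    seed = seed, ...)
  simulate_locus(cfg, default_states(3L, cfg$locus_length))
}

small_params <- function(...) {
  modifyList(list(window_size = 40L, window_overlap = 15L,
                  min_read_valid_bins = 20L), list(...))
}

# Independent average-linkage oracle: recompute every inter-cluster distance
# from the full pairwise matrix at each step (Methods Step 2), same
# lexicographic tie rule as the implementation. O(n^4) but only used at
# small n.
naive_average_linkage <- function(d, t) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > t) {
    best <- NULL
    best_key <- c(Inf, Inf)
    bd <- Inf
    for (p in seq_along(clusters)) {
      for (q in seq_along(clusters)) {
        if (p >= q) next
        cd <- mean(d[clusters[[p]], clusters[[q]]])
        key <- c(min(clusters[[p]][1], clusters[[q]][1]),
                 max(clusters[[p]][1], clusters[[q]][1]))
        if (cd < bd ||
            (cd == bd && (key[1] < best_key[1] ||
                          (key[1] == best_key[1] && key[2] < best_key[2])))) {
          bd <- cd
          best <- c(p, q)
          best_key <- key
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  labels <- integer(n)
  reps <- vapply(clusters, min, integer(1))   # renumber by smallest member
  ord <- order(reps)
  for (k in seq_along(ord)) labels[clusters[[ord[k]]]] <- k
  labels
}

# Brute-force assignment oracle: minimum cost over all permutations.
brute_force_assignment <- function(d) {
  n <- nrow(d)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) !any(duplicated(p))), ,
                 drop = FALSE]
  costs <- apply(perms, 1, function(p) sum(d[cbind(seq_len(n), p)]))
  list(cost = min(costs), perms = perms, costs = costs)
}

# Same-partition check up to label permutation.
same_partition <- function(a, b) {
  isTRUE(all.equal(adjusted_rand_index(a, b), 1))
}

# Write a call table to a temporary TSV.
write_calls_tsv <- function(calls, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(calls, path, sep = "\t", quote = FALSE)
  path
}
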