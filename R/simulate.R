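#' Simulation configuration
#'
#' Defaults describe a realistic nano-NOMe-seq locus: a 50-kb region with
#' GpC sites every ~20 bp (jittered), log-normal read lengths with median
#' 8 kb (well below the locus length, so stitching is exercised), 60x
#' molecule coverage, asymmetric enzymatic/call noise (accessible sites
#' missed at 0.10, protected sites spuriously methylated at 0.05 —
#' methyltransferase under-labelling exceeds spurious labelling), a 5%
#' per-call dropout, and two locus-spanning long reads for leave-one-out
#' validation.
#'
#' @param ... Overrides of the defaults listed above: `locus_length`,
#'   `contig`, `mean_gpc_spacing`, `read_length_median`,
#'   `read_length_sdlog`, `coverage`, `p_fail_meth`, `p_spurious_meth`,
#'   `p_drop`, `n_long_reads`, `min_read_length`, `seed`.
#' @return Named list of simulation parameters.
#' @export
sim_config <- function(...) {
  p <- list(
    locus_length = 50000L,
    contig = "simLocus",
    mean_gpc_spacing = 20,
    read_length_median = 8000,
    read_length_sdlog = 0.6,
    coverage = 60,
    p_fail_meth = 0.10,
    p_spurious_meth = 0.05,
    p_drop = 0.05,
    n_long_reads = 2L,
    min_read_length = 200L,
    seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(p))
  if (length(unknown)) {
    stop("unknown sim_config parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(override)] <- override
  probs <- unlist(p[c("p_fail_meth", "p_spurious_meth", "p_drop")])
  if (any(probs < 0 | probs > 1)) stop("noise probabilities must be in [0, 1]")
  if (p$coverage <= 0) stop("coverage must be positive")
  p
}

#' Default latent accessibility states
#'
#' Builds `n_states` deterministic single-molecule chromatin states over a
#' locus. Each state is a tiling of 147-bp nucleosomes separated by 50-bp
#' accessible linkers, with a state-specific phase offset, overlaid with
#' state-specific nucleosome-free regions (NFRs, 150-400 bp accessible)
#' some of which contain a protected transcription-factor footprint
#' (35-50 bp). The phase offsets and distinct NFR layouts make states
#' distinguishable in (nearly) every clustering window.
#'
#' @param n_states Number of latent states (default 3).
#' @param locus_length Locus length in bp.
#' @param weights Mixing weights; default `c(0.45, 0.35, 0.20)` for three
#'   states, uniform otherwise.
#' @return List of states; each has `id`, `weight`, `intervals`
#'   (`data.table` of start/end/label tiling the locus) and `accessible`
#'   (logical vector of length `locus_length`).
#' @export
default_states <- function(n_states = 3L, locus_length = 50000L,
                           weights = NULL) {
  stopifnot(n_states >= 1, locus_length >= 2000)
  if (is.null(weights)) {
    weights <- if (n_states == 3L) c(0.45, 0.35, 0.20)
               else rep(1 / n_states, n_states)
  }
  stopifnot(length(weights) == n_states, all(weights > 0))
  weights <- weights / sum(weights)

  period <- 197L  # 147 bp nucleosome + 50 bp linker
  lapply(seq_len(n_states), function(k) {
    offset <- ((k - 1L) * 83L) %% period
    pos <- seq_len(locus_length) - 1L
    label <- ifelse(((pos - offset) %% period) < 147L, "nucleosome", "linker")

    # state-specific NFRs, three per state, widths 150-400 bp
    centers <- (c(0.15, 0.45, 0.78) + (k - 1L) * 0.085) %% 0.88 + 0.06
    widths <- 200L + 50L * ((k + seq_along(centers)) %% 4L)
    for (j in seq_along(centers)) {
      s <- max(0L, round(centers[j] * locus_length - widths[j] / 2))
      e <- min(locus_length, s + widths[j])
      label[(s + 1L):e] <- "NFR"
      if ((k + j) %% 2L == 0L) {  # TF footprint inside this NFR
        fw <- 35L + 5L * ((k + j) %% 4L)
        fs <- round((s + e) / 2 - fw / 2)
        label[(fs + 1L):(fs + fw)] <- "TF_footprint"
      }
    }
    accessible <- label %in% c("linker", "NFR")
    r <- rle(label)
    ends <- cumsum(r$lengths)
    intervals <- data.table::data.table(
      start = c(0L, ends[-length(ends)]), end = ends, label = r$values)
    list(id = k, weight = weights[k], intervals = intervals,
         accessible = accessible)
  })
}

#' Simulate a nano-NOMe-seq locus with known latent states
#'
#' Places jittered GpC sites along the locus, draws molecules from the
#' latent state mixture with uniform starts and log-normal lengths clipped
#' to the locus, and emits one methylation call per covered site:
#' methylated iff the site is accessible in the molecule's state, then
#' perturbed by the state-appropriate noise (`p_fail_meth` /
#' `p_spurious_meth`) and dropped with probability `p_drop`. `n_long_reads`
#' additional molecules span the whole locus under the same model. The
#' seed fully determines the output.
#'
#' @param config A [sim_config()].
#' @param states Latent states from [default_states()].
#' @return List with `calls` (a call table as read by
#'   [read_methyl_calls()]), `truth` (`data.table`: read_id, state, start,
#'   end, length, is_long), `region`, `sites`, `states` and `config`.
#' @export
simulate_locus <- function(config = sim_config(),
                           states = default_states(3L, config$locus_length)) {
  set.seed(config$seed)
  L <- config$locus_length
  K <- length(states)
  pi_k <- vapply(states, `[[`, numeric(1), "weight")

  # jittered GpC site placement (gamma inter-site gaps, mean = spacing)
  n_guess <- ceiling(2.5 * L / config$mean_gpc_spacing)
  gaps <- pmax(2, round(stats::rgamma(n_guess, shape = 4,
                                      scale = config$mean_gpc_spacing / 4)))
  sites <- cumsum(gaps)
  sites <- sites[sites < L]
  site_strand <- sample(c("+", "-"), length(sites), replace = TRUE)

  mean_len <- config$read_length_median * exp(config$read_length_sdlog^2 / 2)
  n_reads <- max(1L, ceiling(config$coverage * L / mean_len))

  emit <- function(read_id, state, start, end) {
    in_read <- which(sites >= start & sites < end)
    if (!length(in_read)) return(NULL)
    s <- sites[in_read]
    acc <- states[[state]]$accessible[s + 1L]
    call <- as.integer(acc)
    u <- stats::runif(length(s))
    call[acc & u < config$p_fail_meth] <- 0L
    call[!acc & u < config$p_spurious_meth] <- 1L
    keep <- stats::runif(length(s)) >= config$p_drop
    if (!any(keep)) return(NULL)
    data.table::data.table(
      read_id = read_id, contig = config$contig, position = s[keep],
      strand = site_strand[in_read][keep], call = call[keep],
      confidence = round(stats::runif(sum(keep), 0.8, 1), 4))
  }

  state_of <- sample.int(K, n_reads + config$n_long_reads,
                         replace = TRUE, prob = pi_k)
  starts <- floor(stats::runif(n_reads, 0, L - config$min_read_length))
  lens <- pmax(config$min_read_length,
               round(stats::rlnorm(n_reads, log(config$read_length_median),
                                   config$read_length_sdlog)))
  ends <- pmin(starts + lens, L)

  out <- vector("list", n_reads + config$n_long_reads)
  truth <- vector("list", n_reads + config$n_long_reads)
  for (i in seq_len(n_reads)) {
    id <- sprintf("read_%05d", i)
    out[[i]] <- emit(id, state_of[i], starts[i], ends[i])
    truth[[i]] <- data.table::data.table(
      read_id = id, state = state_of[i], start = starts[i], end = ends[i],
      length = ends[i] - starts[i], is_long = FALSE)
  }
  for (j in seq_len(config$n_long_reads)) {
    i <- n_reads + j
    id <- sprintf("long_%03d", j)
    out[[i]] <- emit(id, state_of[i], 0L, L)
    truth[[i]] <- data.table::data.table(
      read_id = id, state = state_of[i], start = 0L, end = L,
      length = L, is_long = TRUE)
  }
  calls <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  data.table::setorder(calls, read_id, position)
  truth <- data.table::rbindlist(truth)

  list(calls = calls, truth = truth,
       region = region_spec(config$contig, 0, L),
       sites = sites, states = states, config = config)
}

#' Adjusted Rand index between two labellings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabelling), ~0 for independent
#' ones.
#'
#' @param a,b Vectors of labels (any type), equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

#' Score latent-state recovery of a phasing run
#'
#' Compares the final phased labels against the simulated latent states:
#' adjusted Rand index over reads with a series label (pre-assigned
#' extremes, unassigned and filtered reads are excluded and counted),
#' a confusion matrix after optimal series-to-state matching (reusing the
#' assignment solver), and the error between recovered series proportions
#' and the true mixing weights.
#'
#' @param truth Truth table from [simulate_locus()].
#' @param bundle A `phasing_bundle` from [phase_reads()] on the simulated
#'   calls (or its `assignments` table).
#' @return List with `ari`, `confusion` (states x matched series),
#'   `matching` (series id 0-based -> state), `proportion`
#'   (`data.table`: state, true weight, recovered proportion),
#'   `n_scored`, `n_excluded`.
#' @export
score_recovery <- function(truth, bundle) {
  asn <- if (inherits(bundle, "phasing_bundle")) bundle$assignments else bundle
  merged <- merge(asn, truth[, .(read_id, state)], by = "read_id")
  scored <- merged[!merged$label %in%
                     c("FULLY_METH", "FULLY_UNMETH", "UNASSIGNED", "FILTERED")]
  if (nrow(scored) < 2) stop("fewer than 2 scored reads")
  series <- as.integer(scored$label)
  ari <- adjusted_rand_index(scored$state, series)

  state_lv <- sort(unique(truth$state))
  series_lv <- sort(unique(series))
  tab <- table(state = factor(scored$state, levels = state_lv),
               series = factor(series, levels = series_lv))
  # optimal matching of states to series: maximise matched counts
  sq <- max(nrow(tab), ncol(tab))
  cost <- matrix(max(tab) + 1, sq, sq)
  cost[seq_len(nrow(tab)), seq_len(ncol(tab))] <- max(tab) - tab
  state_to_series <- solve_assignment(cost)$assignment  # row i -> column
  rec_count <- vapply(seq_along(state_lv), function(s) {
    j <- state_to_series[s]
    if (j > ncol(tab)) 0L else sum(series == series_lv[j])
  }, integer(1))
  proportion <- data.table::data.table(
    state = state_lv,
    true_weight = truth[, .N, by = state][order(state), N / sum(N)],
    recovered_count = rec_count,
    recovered = rec_count / nrow(scored))

  list(ari = ari, confusion = tab,
       matching = stats::setNames(
         series_lv[pmin(state_to_series[seq_along(state_lv)], ncol(tab))],
         state_lv),
       proportion = proportion,
       n_scored = nrow(scored), n_excluded = nrow(merged) - nrow(scored))
}
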