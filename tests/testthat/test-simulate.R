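test_that("simulation is deterministic under the seed", {
  a <- simulate_locus(sim_config(locus_length = 8000L, coverage = 20,
                                 read_length_median = 2000, seed = 61),
                      default_states(3, 8000L))
  b <- simulate_locus(sim_config(locus_length = 8000L, coverage = 20,
                                 read_length_median = 2000, seed = 61),
                      default_states(3, 8000L))
  expect_identical(as.data.frame(a$calls), as.data.frame(b$calls))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c <- simulate_locus(sim_config(locus_length = 8000L, coverage = 20,
                                 read_length_median = 2000, seed = 62),
                      default_states(3, 8000L))
  expect_false(identical(as.data.frame(a$calls), as.data.frame(c$calls)))
})

test_that("noise-free extreme states emit pure calls", {
  L <- 5000L
  all_open <- list(list(id = 1, weight = 1,
                        accessible = rep(TRUE, L),
                        intervals = data.table(start = 0L, end = L,
                                               label = "NFR")))
  cfg <- sim_config(locus_length = L, coverage = 10,
                    read_length_median = 1000, p_fail_meth = 0,
                    p_spurious_meth = 0, p_drop = 0, n_long_reads = 0L,
                    seed = 67)
  sim <- simulate_locus(cfg, all_open)
  expect_true(all(sim$calls$call == 1L))
  all_closed <- all_open
  all_closed[[1]]$accessible <- rep(FALSE, L)
  sim2 <- simulate_locus(cfg, all_closed)
  expect_true(all(sim2$calls$call == 0L))
})

test_that("state draws follow the mixing weights", {
  # ~2000 molecules at pi = (0.5, 0.5): counts within the binomial 99% CI
  cfg <- sim_config(locus_length = 5000L, coverage = 240,
                    read_length_median = 600, read_length_sdlog = 0.3,
                    n_long_reads = 0L, seed = 71)
  states <- default_states(2, 5000L, weights = c(0.5, 0.5))
  sim <- simulate_locus(cfg, states)
  n <- nrow(sim$truth)
  expect_gte(n, 1500)
  k <- sum(sim$truth$state == 1L)
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(k, ci[1]); expect_lte(k, ci[2])
})

test_that("per-site methylation matches the analytic mixture expectation", {
  cfg <- sim_config(locus_length = 6000L, coverage = 120,
                    read_length_median = 1500, n_long_reads = 0L, seed = 73)
  states <- default_states(3, 6000L)
  sim <- simulate_locus(cfg, states)
  pi_k <- vapply(states, `[[`, numeric(1), "weight")
  acc <- vapply(states, function(st) st$accessible[sim$sites + 1L],
                logical(length(sim$sites)))
  # emission model: conditional on each read's latent state, a call is
  # methylated with prob 1 - p_fail (accessible) or p_spurious (protected)
  st_of <- sim$truth$state[match(sim$calls$read_id, sim$truth$read_id)]
  site_idx <- match(sim$calls$position, sim$sites)
  acc_call <- acc[cbind(site_idx, st_of)]
  expected <- mean(ifelse(acc_call, 1 - cfg$p_fail_meth,
                          cfg$p_spurious_meth))
  observed <- mean(sim$calls$call)
  expect_lt(abs(observed - expected), 0.01)  # ~40k Bernoulli: MC sd ~0.002
  # and the pi-weighted mixture expectation at the read-mixture scale
  p_mix <- mean(acc %*% (pi_k * (1 - cfg$p_fail_meth)) +
                  (!acc) %*% (pi_k * cfg$p_spurious_meth))
  expect_lt(abs(observed - p_mix), 0.05)
})

test_that("default states tile the locus and stay distinguishable", {
  states <- default_states(3, 20000L)
  for (st in states) {
    expect_equal(st$intervals$start[1], 0L)
    expect_equal(st$intervals$end[nrow(st$intervals)], 20000L)
    # contiguous, non-overlapping intervals
    expect_equal(st$intervals$start[-1],
                 st$intervals$end[-nrow(st$intervals)])
    expect_setequal(setdiff(unique(st$intervals$label),
                            c("nucleosome", "linker", "NFR", "TF_footprint")),
                    character(0))
    # footprints live inside accessible context and are 35-50 bp
    fp <- st$intervals[label == "TF_footprint"]
    if (nrow(fp)) expect_true(all(fp$end - fp$start >= 35 &
                                    fp$end - fp$start <= 50))
  }
  expect_equal(sum(vapply(states, `[[`, numeric(1), "weight")), 1)
  # states differ over a sizeable fraction of the locus
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gt(mean(states[[i]]$accessible != states[[j]]$accessible), 0.2)
  }
})

test_that("adjusted_rand_index behaves at the extremes and matches igraph", {
  a <- rep(1:3, each = 40)
  expect_equal(adjusted_rand_index(a, a), 1)
  perm <- c(2L, 3L, 1L)[a]  # relabelled partition is still perfect
  expect_equal(adjusted_rand_index(a, perm), 1)
  set.seed(79)
  expect_lt(abs(adjusted_rand_index(a, sample(a))), 0.1)
  skip_if_not_installed("igraph")
  for (rep in 1:5) {
    x <- sample(1:4, 60, TRUE)
    y <- sample(1:3, 60, TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 igraph::compare(x, y, method = "adjusted.rand"),
                 tolerance = 1e-12)
  }
})

test_that("score_recovery computes ARI, matching and proportions", {
  sim <- small_sim(seed = 83)
  bundle <- phase_reads(sim$calls, sim$region, 3, small_params())
  sc <- score_recovery(sim$truth, bundle)
  expect_gte(sc$ari, 0.8)
  expect_equal(sum(sc$proportion$recovered), 1, tolerance = 1e-12)
  expect_equal(sc$n_scored + sc$n_excluded, nrow(bundle$assignments))
  # perfect assignment gives ARI 1 by construction
  perfect <- data.table(read_id = sim$truth$read_id,
                        label = as.character(sim$truth$state - 1L))
  expect_equal(score_recovery(sim$truth, perfect)$ari, 1)
})
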