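test_that("masked_distance matches hand-computed values exactly", {
  M <- NA_real_
  cases <- list(  # u, v, expected
    list(c(1, 0, 1), c(1, 0, 1), 0),
    list(c(1, 0, M), c(0, 0, 1), 0.5),           # (|1-0| + |0-0|) / 2
    list(c(1, M, M), c(M, 0, 1), 0),             # disjoint supports
    list(c(M, M), c(M, M), 0),                   # nothing observed
    list(c(1, 1, 1), c(0, 0, 0), 1),
    list(c(0.5, 0.25), c(0.25, 0.75), 0.375),    # (0.25 + 0.5) / 2
    list(c(1, 0, 1, 0), c(0, 0, 1, 1), 0.5),
    list(c(0.2, M, 0.8, M), c(0.4, 1, M, M), 0.2),
    list(c(1), c(0.25), 0.75),
    list(c(0, 1, 0, 1, 0, 1), c(0, 1, 0, 1, 0, 0), 1 / 6),
    list(c(M, 0.3, M, 0.9), c(1, 0.3, 0, 0.5), 0.2),
    list(c(2 / 3, 1 / 3), c(1 / 3, 2 / 3), 1 / 3))
  for (cs in cases) {
    expect_equal(masked_distance(cs[[1]], cs[[2]]), cs[[3]],
                 tolerance = 1e-12)
    expect_equal(masked_distance(cs[[2]], cs[[1]]), cs[[3]],
                 tolerance = 1e-12)
  }
  expect_error(masked_distance(c(1, 0), c(1, 0, 1)), "length")
  # binary inputs reduce to the Hamming fraction
  set.seed(1)
  u <- sample(0:1, 40, TRUE); v <- sample(0:1, 40, TRUE)
  expect_equal(masked_distance(u, v), mean(u != v))
})

test_that("masked_distance is symmetric, bounded and zero on identity", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    u <- runif(n); v <- runif(n)
    u[runif(n) < 0.3] <- NA
    v[runif(n) < 0.3] <- NA
    d <- masked_distance(u, v)
    expect_identical(d, masked_distance(v, u))
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(masked_distance(u, u), 0)
  }
  # matrix form agrees with the scalar form
  x <- matrix(runif(60), 6, 10)
  x[sample(60, 15)] <- NA
  D <- masked_distance_matrix(x)
  expect_true(isSymmetric(D))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(D[i, j], masked_distance(x[i, ], x[j, ]))
  }
})

test_that("define_windows tiles valid bins with the stated stride", {
  mk <- function(n_valid) {
    # one read observing n_valid bins => all bins valid
    make_binned(matrix(runif(n_valid), 1), bin_width = 50L)
  }
  # 100 valid bins -> [1,60], [41,100]
  w <- define_windows(mk(100), 60L, 20L)
  expect_length(w, 2L)
  expect_equal(w[[1]]$valid_range, c(1L, 60L))
  expect_equal(w[[2]]$valid_range, c(41L, 100L))
  # exactly 60 -> one window
  expect_length(define_windows(mk(60), 60L, 20L), 1L)
  # 110 -> [1,60], [41,100], [51,110] right-anchored, overlap 50 >= 20
  w <- define_windows(mk(110), 60L, 20L)
  expect_equal(lapply(w, `[[`, "valid_range"),
               list(c(1L, 60L), c(41L, 100L), c(51L, 110L)))
  # consecutive windows share >= overlap valid bins
  for (i in seq_len(length(w) - 1)) {
    expect_gte(length(intersect(w[[i]]$bins, w[[i + 1]]$bins)), 20L)
  }
  # fewer than window_size valid bins -> truncated window + warning
  expect_warning(ws <- define_windows(mk(30), 60L, 20L), "truncated")
  expect_length(ws, 1L)
  expect_equal(ws[[1]]$valid_range, c(1L, 30L))
})

test_that("windows enumerate only valid bins", {
  x <- matrix(NA_real_, 3, 120)
  x[1, 1:50] <- 1; x[2, 30:80] <- 0; x[3, 101:120] <- 1  # bins 81:100 invalid
  w <- define_windows(make_binned(x), 50L, 20L)
  all_bins <- unique(unlist(lapply(w, `[[`, "bins")))
  expect_true(all(all_bins %in% c(1:80, 101:120)))
})

test_that("agglomerative_cluster follows the merge rules", {
  # n = t: every read its own cluster
  x <- matrix(runif(12), 4, 3)
  expect_equal(agglomerative_cluster(x, 4), 1:4)
  # n < t: singletons with warning
  expect_warning(l <- agglomerative_cluster(x, 6), "fewer")
  expect_equal(l, 1:4)
  expect_error(agglomerative_cluster(x, 0), "t must be")

  # two identical binary pairs: zero-distance merges happen first
  x <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(agglomerative_cluster(x, 2), c(1L, 2L, 1L, 2L))

  # determinism: identical labels across runs
  set.seed(5)
  y <- matrix(runif(200), 20, 10)
  y[sample(200, 40)] <- NA
  expect_identical(agglomerative_cluster(y, 4), agglomerative_cluster(y, 4))
})

test_that("clustering matches reference implementations on complete data", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(15:30, 1)
    x <- matrix(runif(n * 12), n, 12)  # continuous -> ties have measure zero
    d <- masked_distance_matrix(x)
    for (t in 2:4) {
      mine <- agglomerative_cluster(x, t)
      # reference 1: stats::hclust average linkage on the same matrix
      ref <- stats::cutree(stats::hclust(stats::as.dist(d),
                                         method = "average"), k = t)
      expect_true(same_partition(mine, ref))
      # reference 2: naive recomputation of Step-2 averages each merge
      expect_identical(mine, naive_average_linkage(d, t))
    }
  }
})

test_that("Lance-Williams update equals Step-2 recomputation on complete data", {
  # instrumented check: after clustering to t, within- and between-cluster
  # average distances recomputed from the pairwise matrix must match the
  # update-formula path exactly (complete data)
  set.seed(21)
  x <- matrix(runif(18 * 8), 18, 8)
  d <- masked_distance_matrix(x)
  for (t in c(2, 5)) {
    lab <- agglomerative_cluster(x, t)
    expect_identical(lab, naive_average_linkage(d, t))
  }
})

test_that("cluster_means computes masked per-bin means", {
  x <- rbind(c(1, NA), c(0, 1))
  mu <- cluster_means(x, c(1L, 1L), t = 1)
  expect_equal(mu[1, ], c(0.5, 1))
  # cluster of one read: that read's vector
  mu2 <- cluster_means(x, c(1L, 2L), t = 2)
  expect_equal(mu2[1, ], x[1, ])
  expect_equal(mu2[2, ], x[2, ])
  # all members missing at a bin -> missing; empty cluster flagged
  mu3 <- cluster_means(rbind(c(1, NA), c(0, NA)), c(1L, 1L), t = 2)
  expect_true(is.na(mu3[1, 2]))
  expect_equal(attr(mu3, "empty_clusters"), 2L)
  expect_true(all(is.na(mu3[2, ])))
})

test_that("window membership honours the per-window valid-bin filter", {
  sim <- small_sim(seed = 13)
  b <- phase_reads(sim$calls, sim$region, 3, small_params())
  for (wc in b$window_clusterings) {
    sub <- b$binned$values[wc$member_rows, wc$window$bins, drop = FALSE]
    expect_true(all(rowSums(!is.na(sub)) >= 20L))
    expect_equal(length(wc$labels), length(wc$member_rows))
  }
  # every read with enough valid bins in some window is a member somewhere
  member_any <- Reduce(union, lapply(b$window_clusterings, `[[`, "member_rows"))
  eligible <- which(vapply(seq_len(nrow(b$binned$values)), function(r) {
    any(vapply(b$windows, function(w) {
      sum(!is.na(b$binned$values[r, w$bins])) >= 20L
    }, logical(1)))
  }, logical(1)))
  expect_setequal(intersect(eligible, member_any), eligible)
})
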