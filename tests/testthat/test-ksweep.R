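test_that("replicate statistics implement the mean, Bessel sd and c_v exactly", {
  expect_identical(replicate_mean(c(5, 5, 5)), 5)
  expect_identical(replicate_mean(1:10), 5.5)
  expect_identical(replicate_sd(rep(3.2, 10)), 0)
  # direct evaluation of the 1/(n-1) formula for 1..10
  expect_equal(replicate_sd(1:10), sqrt(82.5 / 9))
  expect_equal(relative_sd(1:10), sqrt(82.5 / 9) / 5.5)
  expect_identical(relative_sd(rep(7, 4)), 0)
  expect_error(replicate_mean(numeric(0)), "empty")
  expect_error(replicate_sd(3), "at least 2")
  expect_error(relative_sd(c(-1, 1)), "mean is zero")
})

test_that("replicate statistics agree with textbook two-pass oracles and scale laws", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- runif(sample(c(10, 100, 10000), 1), 1, 500)
    expect_equal(replicate_mean(x), sum(x) / length(x), tolerance = 1e-12)
    expect_equal(replicate_sd(x), stats::sd(x), tolerance = 1e-12)
    expect_equal(relative_sd(x), stats::sd(x) / mean(x), tolerance = 1e-12)
    c0 <- runif(1, 0.5, 10)
    # sd is scale-equivariant, c_v scale-invariant
    expect_equal(replicate_sd(c0 * x), c0 * replicate_sd(x))
    expect_equal(relative_sd(c0 * x), relative_sd(x))
  }
})

test_that("the mean deviation from the sample mean vanishes numerically", {
  expect_identical(expected_deviation_check(c(1, 2, 3)), 0)
  for (seed in 1:5) {
    set.seed(seed)
    x <- rpois(1e4, 100) + runif(1e4)
    r <- expected_deviation_check(x)
    expect_lte(abs(r), 1e-9 * max(1, abs(mean(x))))
    # compensated-summation oracle: the residual is pure rounding noise
    expect_lte(abs(kahan_sum(x - mean(x)) / length(x)),
               1e-9 * max(1, abs(mean(x))))
  }
})

test_that("build_averaged_replicate averages fiber counts with both presence semantics", {
  r1 <- mk_graph(3, data.frame(u = 1, v = 2, fiber_count = 4,
                               mean_length = 40, mean_fa = 0.4))
  r2 <- mk_graph(3, data.frame(u = 1, v = 2, fiber_count = 6,
                               mean_length = 60, mean_fa = 0.6))
  # k = 1: the replicate is the run itself
  expect_true(braingraph_equal(build_averaged_replicate(list(r1)), r1))
  avg <- build_averaged_replicate(list(r1, r2))
  expect_identical(avg$edges$fiber_count, 5)
  expect_identical(avg$edges$mean_length, 50)

  # an edge absent from one run: counted as zero under "any", dropped under "all"
  r3 <- braingraph(mk_nodes(3))
  avg_any <- build_averaged_replicate(list(r1, r3), "any")
  expect_identical(avg_any$edges$fiber_count, 2)
  expect_identical(n_edges(build_averaged_replicate(list(r1, r3), "all")), 0L)

  # k = 5 simulated runs match a brute-force per-edge accumulation
  gt <- make_ground_truth(n_nodes = 6, edge_density = 0.6, seed = 21)
  runs <- simulate_runs(gt, n_runs = 5, seed = 21)
  avg5 <- build_averaged_replicate(runs, "any")
  for (i in seq_len(nrow(avg5$edges))) {
    tot <- 0
    for (r in runs) {
      hit <- which(r$edges$u == avg5$edges$u[i] & r$edges$v == avg5$edges$v[i])
      if (length(hit)) tot <- tot + r$edges$fiber_count[hit]
    }
    expect_equal(avg5$edges$fiber_count[i], tot / 5)
  }
})

test_that("a zero-noise source gives zero c_v for every edge at every k", {
  gt <- make_ground_truth(n_nodes = 6, edge_density = 0.6, seed = 9,
                          noise = "none")
  gt$edges$detection_p <- 1
  sw <- k_sweep(gt, k_values = c(1, 2, 5), n_replicates = 4, seed = 9)
  expect_identical(nrow(sw$summary), 3L)
  expect_true(all(sw$per_edge$cv == 0))
  expect_true(all(sw$summary$median == 0))
  expect_identical(unique(sw$per_edge[sw$per_edge$k == 1, "u"]),
                   unique(sw$per_edge[sw$per_edge$k == 5, "u"]))
})

test_that("k-sweep results keep only all-replicate edges and reproduce bit-for-bit", {
  gt <- make_ground_truth(n_nodes = 6, edge_density = 0.6, seed = 13,
                          parameter_ranges = within(default_parameter_ranges(),
                                                    detection_p <- c(0.5, 0.9)))
  sw <- k_sweep(gt, k_values = c(1, 3), n_replicates = 5, seed = 13)
  # edge-retention rule: every reported edge occurs in all replicate graphs
  for (k in c(1, 3)) {
    reps <- lapply(1:5, function(i) {
      runs <- simulate_runs(gt, n_runs = k,
                            seed = braincons:::derive_seed(13, k, i))
      build_averaged_replicate(runs, "any")
    })
    common <- Reduce(intersect, lapply(reps, function(g) edge_keys(g$edges)))
    pe <- sw$per_edge[sw$per_edge$k == k, ]
    expect_setequal(paste(pe$u, pe$v, sep = ":"), common)
  }
  sw2 <- k_sweep(gt, k_values = c(1, 3), n_replicates = 5, seed = 13)
  expect_identical(sw, sw2)
  # run_source may also be a generator function
  sw3 <- k_sweep(function(n, s) simulate_runs(gt, n_runs = n, seed = s),
                 k_values = c(1, 3), n_replicates = 5, seed = 13)
  expect_identical(sw$per_edge, sw3$per_edge)
})

test_that("per-edge c_v is extractable as a convergence curve over k", {
  gt <- make_ground_truth(n_nodes = 4, edge_density = 1, seed = 31)
  gt$edges$detection_p <- 1
  sw <- k_sweep(gt, k_values = c(1, 2, 4, 8), n_replicates = 8, seed = 31)
  cur <- cv_curve(sw, gt$edges$u[1], gt$edges$v[1])
  expect_identical(cur$k, c(1L, 2L, 4L, 8L))
  expect_true(all(cur$cv >= 0))
  # averaging more runs shrinks the variability overall
  expect_lt(cur$cv[4], cur$cv[1])
  expect_error(cv_curve(sw, 1, 999), "not present")
})

test_that("quartile summaries follow the median-of-halves convention", {
  gt <- make_ground_truth(n_nodes = 8, edge_density = 0.9, seed = 17)
  gt$edges$detection_p <- 1
  sw <- k_sweep(gt, k_values = 2, n_replicates = 6, seed = 17)
  cv <- sw$per_edge$cv
  s <- sort(cv)
  h <- floor(length(s) / 2)
  expect_equal(sw$summary$q1, median(s[seq_len(h)]))
  expect_equal(sw$summary$q3, median(s[seq.int(length(s) - h + 1, length(s))]))
  expect_equal(sw$summary$median, median(cv))
  expect_equal(sw$summary$min, min(cv))
  expect_equal(sw$summary$max, max(cv))
})

test_that("recommend_k picks the first k whose improvement falls below tolerance", {
  fake <- function(med, k) {
    structure(list(summary = data.frame(k = k, median = med)),
              class = "ksweep_result")
  }
  expect_identical(recommend_k(fake(c(0.4, 0.2, 0.19, 0.189), c(1, 5, 10, 20)),
                               0.1), 5)
  expect_identical(recommend_k(fake(rep(0.3, 4), c(1, 5, 10, 20)), 0.1), 1)
  expect_warning(
    krec <- recommend_k(fake(c(0.8, 0.4, 0.2, 0.1), c(1, 2, 4, 8)), 0.1),
    "still improving")
  expect_identical(krec, 8)
  expect_error(recommend_k(fake(0.4, 1)), "at least 2")

  # agrees with a brute-force re-evaluation of the rule on a simulated sweep
  gt <- make_ground_truth(n_nodes = 5, edge_density = 0.8, seed = 23)
  gt$edges$detection_p <- 1
  sw <- k_sweep(gt, k_values = c(1, 2, 4, 8, 16, 32), n_replicates = 12,
                seed = 23)
  med <- as.numeric(stats::runmed(sw$summary$median, 3, endrule = "keep"))
  tol <- 0.2
  scan <- NA
  for (j in seq_len(length(med) - 1)) {
    if ((med[j] - med[j + 1]) / med[j] < tol) {
      scan <- sw$summary$k[j]
      break
    }
  }
  if (is.na(scan)) {
    expect_warning(expect_identical(recommend_k(sw, tol), max(sw$summary$k)))
  } else {
    expect_identical(recommend_k(sw, tol), scan)
  }
})
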