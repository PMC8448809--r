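one_edge_run <- function(fc, ml = 40, fa = 0.5, n_nodes = 3) {
  mk_graph(n_nodes, data.frame(u = 1, v = 2, fiber_count = fc,
                               mean_length = ml, mean_fa = fa))
}

test_that("collect_samples gathers per-edge observations across runs", {
  runs <- lapply(rep(5, 10), one_edge_run)
  tab <- collect_samples(runs)
  expect_identical(length(tab$u), 1L)
  expect_identical(runs_present(tab), 10L)
  expect_identical(tab$samples[[1]]$fiber_count, rep(5, 10))
  expect_identical(tab$samples[[1]]$run, 1:10)

  # edge missing from the last run
  runs2 <- c(lapply(rep(5, 9), one_edge_run), list(braingraph(mk_nodes(3))))
  expect_identical(runs_present(collect_samples(runs2)), 9L)

  expect_error(collect_samples(runs[1]), "at least 2 runs")
  bad <- c(runs[1:9], list(one_edge_run(5, n_nodes = 4)))
  expect_error(collect_samples(bad), "run 10")
})

test_that("collect_samples matches an exhaustive pair-by-run scan on random runs", {
  for (seed in 1:3) {
    runs <- rand_runs(5, 3, seed = seed)
    tab <- collect_samples(runs)
    # brute force over all pairs and runs
    for (a in 1:5) for (b in 1:5) {
      if (a >= b) next
      expected <- NULL
      for (r in 1:3) {
        e <- runs[[r]]$edges
        hit <- which(e$u == a & e$v == b)
        if (length(hit))
          expected <- rbind(expected,
                            data.frame(run = r, fc = e$fiber_count[hit]))
      }
      i <- which(tab$u == a & tab$v == b)
      if (is.null(expected)) {
        expect_length(i, 0)
      } else {
        expect_identical(tab$samples[[i]]$run, expected$run)
        expect_identical(tab$samples[[i]]$fiber_count, expected$fc)
      }
    }
  }
})

test_that("the presence filter keeps exactly the edges seen in enough runs", {
  runs <- c(lapply(rep(5, 9), one_edge_run), list(braingraph(mk_nodes(3))))
  tab <- collect_samples(runs)
  # present in 9 of 10 runs: removed under the all-runs default
  expect_identical(length(filter_consensus_edges(tab)$u), 0L)
  expect_identical(length(filter_consensus_edges(
    tab, consensus_policy(required_presence = 9))$u), 1L)

  # all edges in all runs: identity
  runs_full <- lapply(rep(c(5, 7, 9, 2, 8, 3, 6, 4, 1, 10), 1), one_edge_run)
  tab2 <- collect_samples(runs_full)
  expect_identical(filter_consensus_edges(tab2)$u, tab2$u)

  # random 10-run set: survivors equal the brute-force edge-set intersection
  runs3 <- rand_runs(8, 10, seed = 11, p_edge = 0.7)
  surv <- filter_consensus_edges(collect_samples(runs3))
  inter <- Reduce(intersect, lapply(runs3, function(g)
    paste(g$edges$u, g$edges$v, sep = ":")))
  expect_setequal(paste(surv$u, surv$v, sep = ":"), inter)
})

test_that("trim_extremes deletes one minimum and one maximum deterministically", {
  tr <- trim_extremes(1:10)
  expect_length(tr$retained, 8)
  expect_equal(mean(tr$retained), 5.5)
  expect_identical(sort(tr$retained), as.integer(2:9))
  expect_identical(sort(tr$dropped_indices), c(1L, 10L))

  # constant vector: one min-5 and one max-5 dropped, lowest indices first
  trc <- trim_extremes(rep(5, 10))
  expect_identical(trc$retained, rep(5, 8))
  expect_identical(trc$dropped_indices, c(1L, 2L))

  # generalized trims
  tr2 <- trim_extremes(1:10, n_trim_low = 2, n_trim_high = 3)
  expect_identical(sort(tr2$retained), as.integer(3:7))

  expect_error(trim_extremes(c(1, 2)), "more than")
  # retained values stay within the raw range
  for (seed in 1:20) {
    set.seed(seed)
    x <- sample(1:30, 10, replace = TRUE)
    r <- trim_extremes(x)$retained
    expect_gte(min(r), min(x))
    expect_lte(max(r), max(x))
    expect_gte(mean(r), min(x))
    expect_lte(mean(r), max(x))
  }
})

test_that("aggregate_edge trims fiber counts and averages the three weights", {
  entry <- data.frame(run = 1:10, fiber_count = 1:10,
                      mean_length = rep(40, 10), mean_fa = rep(0.5, 10))
  w <- aggregate_edge(entry)
  expect_equal(unname(w), c(5.5, 40, 0.5))

  entry2 <- data.frame(run = 1:10, fiber_count = rep(3, 10),
                       mean_length = runif(10, 30, 50),
                       mean_fa = runif(10, 0.3, 0.7))
  expect_identical(unname(aggregate_edge(entry2)["fiber_count"]), 3)

  # random entries equal an independent sort-drop-average recomputation
  for (seed in 1:20) {
    set.seed(seed)
    e <- data.frame(run = 1:10,
                    fiber_count = sample(1:15, 10, replace = TRUE),
                    mean_length = runif(10, 20, 100),
                    mean_fa = runif(10, 0.2, 0.8))
    o <- e[order(e$fiber_count, e$mean_length, e$mean_fa, e$run), ][2:9, ]
    expect_equal(unname(aggregate_edge(e)),
                 c(mean(o$fiber_count), mean(o$mean_length), mean(o$mean_fa)))
    # the all-runs length/FA population switch
    w_all <- aggregate_edge(e, consensus_policy(length_fa_population = "all"))
    expect_equal(unname(w_all["mean_length"]), mean(e$mean_length))
    expect_equal(unname(w_all["mean_fa"]), mean(e$mean_fa))
  }
})

test_that("build_consensus is a fixed point on identical runs and drops private edges", {
  run <- mk_graph(4, data.frame(u = c(1, 2, 3), v = c(2, 3, 4),
                                fiber_count = c(4, 9, 2),
                                mean_length = c(30, 60, 90),
                                mean_fa = c(0.3, 0.5, 0.7)))
  cons <- build_consensus(rep(list(run), 10))
  expect_true(braingraph_equal(run, cons))
  expect_identical(cons$provenance$stage, "consensus")
  expect_identical(cons$provenance$n_runs, 10L)

  # a run with one extra private edge: that edge is absent from consensus
  extra <- run
  extra$edges <- rbind(extra$edges,
                       data.frame(u = 1L, v = 4L, fiber_count = 5,
                                  mean_length = 50, mean_fa = 0.5))
  runs <- c(rep(list(run), 9), list(braingraph(extra$nodes, extra$edges)))
  cons2 <- build_consensus(runs)
  expect_true(braingraph_equal(run, cons2))

  # degenerate config fails loudly instead of averaging nothing
  expect_error(build_consensus(rep(list(run), 2)), "degenerate")
  expect_error(consensus_policy(required_presence = 0), "positive")
})

test_that("build_consensus equals the monolithic brute-force oracle on random instances", {
  for (seed in 1:25) {
    n_nodes <- sample(4:12, 1)
    runs <- rand_runs(n_nodes, 10, seed = 1000 + seed, p_edge = 0.75)
    cons <- build_consensus(runs)
    exp_e <- oracle_consensus(runs)
    if (is.null(exp_e)) {
      expect_identical(n_edges(cons), 0L)
    } else {
      expect_identical(cons$edges$u, exp_e$u)
      expect_identical(cons$edges$v, exp_e$v)
      expect_equal(cons$edges$fiber_count, exp_e$fiber_count)
      expect_equal(cons$edges$mean_length, exp_e$mean_length)
      expect_equal(cons$edges$mean_fa, exp_e$mean_fa)
    }
  }
})

test_that("consensus weights are invariant under run permutation and shrink monotonically", {
  for (seed in 1:5) {
    runs <- rand_runs(8, 10, seed = 2000 + seed, p_edge = 0.8)
    cons <- build_consensus(runs)
    set.seed(seed)
    perm <- sample(10)
    cons_p <- build_consensus(runs[perm])
    expect_true(braingraph_equal(cons, cons_p))

    # adding a run can only shrink or preserve the consensus edge set
    extra <- rand_runs(8, 11, seed = 3000 + seed, p_edge = 0.8)[[11]]
    cons11 <- build_consensus(c(runs, list(extra)))
    expect_true(all(edge_keys(cons11$edges) %in% edge_keys(cons$edges)))
  }
})
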