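# Fixture builders and independent brute-force oracles used across tests.
# The oracles re-derive expected results by exhaustive enumeration and never
# share code with the package internals they check.

mk_nodes <- function(n) {
  data.frame(
    id = seq_len(n),
    label = sprintf("r%03d", seq_len(n)),
    hemisphere = rep_len(c("left", "right"), n),
    x = as.numeric(seq_len(n)), y = numeric(n), z = numeric(n),
    stringsAsFactors = FALSE
  )
}

mk_graph <- function(n_nodes, edges, ...) {
  braingraph(mk_nodes(n_nodes), edges, ...)
}

# random per-run braingraphs on a shared node set, independent of the
# package's tractography simulator
rand_runs <- function(n_nodes, n_runs, seed, p_edge = 0.4) {
  set.seed(seed)
  nodes <- mk_nodes(n_nodes)
  pairs <- t(combn(n_nodes, 2))
  lapply(seq_len(n_runs), function(r) {
    pick <- runif(nrow(pairs)) < p_edge
    m <- sum(pick)
    e <- if (m) data.frame(
      u = pairs[pick, 1], v = pairs[pick, 2],
      fiber_count = as.numeric(sample(1:50, m, replace = TRUE)),
      mean_length = runif(m, 20, 120),
      mean_fa = runif(m, 0.2, 0.8)
    ) else data.frame(u = integer(0), v = integer(0),
                      fiber_count = numeric(0), mean_length = numeric(0),
                      mean_fa = numeric(0))
    braingraph(nodes, e, provenance = list(run = r))
  })
}

# monolithic brute-force consensus: scan every node pair over every run,
# keep pairs present in >= req runs, sort observations lexicographically,
# drop extremes of the fiber count, average
oracle_consensus <- function(runs, n_trim_low = 1, n_trim_high = 1,
                             required = length(runs)) {
  ids <- runs[[1]]$nodes$id
  rows <- list()
  for (a in ids) for (b in ids) {
    if (a >= b) next
    obs <- NULL
    for (r in seq_along(runs)) {
      e <- runs[[r]]$edges
      hit <- which((e$u == a & e$v == b) | (e$u == b & e$v == a))
      if (length(hit) == 1)
        obs <- rbind(obs, data.frame(run = r, fc = e$fiber_count[hit],
                                     ml = e$mean_length[hit],
                                     fa = e$mean_fa[hit]))
    }
    if (!is.null(obs) && nrow(obs) >= required) {
      o <- obs[order(obs$fc, obs$ml, obs$fa, obs$run), ]
      keep <- o[seq.int(1 + n_trim_low, nrow(o) - n_trim_high), ]
      rows[[length(rows) + 1]] <- data.frame(
        u = a, v = b, fiber_count = mean(keep$fc),
        mean_length = mean(keep$ml), mean_fa = mean(keep$fa))
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# brute-force vertex contraction: double loop over fine edges accumulating
# fiber mass and weighted sums into coarse pairs
oracle_contract <- function(graph, labmap) {
  lab <- graph$nodes$label
  coarse_of <- function(id) unname(labmap[[lab[match(id, graph$nodes$id)]]])
  acc <- new.env()
  dropped <- 0
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    ca <- coarse_of(e$u)
    cb <- coarse_of(e$v)
    if (ca == cb) {
      dropped <- dropped + e$fiber_count
      next
    }
    key <- paste(sort(c(ca, cb)), collapse = "|")
    prev <- if (exists(key, acc)) get(key, acc) else c(0, 0, 0)
    assign(key, prev + c(e$fiber_count, e$fiber_count * e$mean_length,
                         e$fiber_count * e$mean_fa), acc)
  }
  keys <- sort(ls(acc))
  edges <- NULL
  for (key in keys) {
    v <- get(key, acc)
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    edges <- rbind(edges, data.frame(
      a = ab[1], b = ab[2], fiber_count = v[1],
      mean_length = v[2] / v[1], mean_fa = v[3] / v[1]))
  }
  list(edges = edges, self_loop_mass = dropped)
}

# a consistent 3-level test hierarchy over the mk_nodes labels
mk_hierarchy <- function(n_fine, n_mid, n_coarse) {
  stopifnot(n_fine > n_mid, n_mid > n_coarse)
  mid <- sprintf("m%02d", sort(rep_len(seq_len(n_mid), n_fine)))
  coarse_of_mid <- sort(rep_len(seq_len(n_coarse), n_mid))
  parcellation_hierarchy(data.frame(
    fine = sprintf("r%03d", seq_len(n_fine)),
    mid = mid,
    coarse = sprintf("c%02d", coarse_of_mid[as.integer(sub("m", "", mid))]),
    stringsAsFactors = FALSE
  ))
}

# compensated (Kahan) summation oracle for numerical-stability checks
kahan_sum <- function(x) {
  s <- 0
  c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}
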