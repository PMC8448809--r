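#' Consensus aggregation policy
#'
#' Controls how per-run braingraphs are merged into one consensus graph:
#' how many runs an edge must appear in to be kept, and how many extremal
#' fiber-count observations are discarded before averaging. The defaults
#' encode the standard 10-repetition workflow: an edge must be present in
#' all runs, and one minimal plus one maximal fiber count are deleted (so
#' 10 runs leave 8 values to average).
#'
#' @param required_presence `"all"` (default) or an integer: minimum number
#'   of runs an edge must appear in.
#' @param n_trim_low,n_trim_high number of smallest / largest fiber-count
#'   observations to discard per edge (defaults 1 and 1).
#' @param length_fa_population `"trimmed"` (default) averages streamline
#'   lengths and FA over the runs that survive the fiber-count trim;
#'   `"all"` averages them over every run the edge appears in.
#' @return an object of class `consensus_policy`.
#' @export
consensus_policy <- function(required_presence = "all",
                             n_trim_low = 1L, n_trim_high = 1L,
                             length_fa_population = c("trimmed", "all")) {
  if (!(identical(required_presence, "all") ||
        (is.numeric(required_presence) && required_presence >= 1)))
    stop_input("required_presence must be \"all\" or a positive integer")
  n_trim_low <- as.integer(n_trim_low)
  n_trim_high <- as.integer(n_trim_high)
  if (n_trim_low < 0 || n_trim_high < 0)
    stop_input("trim counts must be non-negative")
  structure(
    list(required_presence = required_presence,
         n_trim_low = n_trim_low, n_trim_high = n_trim_high,
         length_fa_population = match.arg(length_fa_population)),
    class = "consensus_policy"
  )
}

#' @export
print.consensus_policy <- function(x, ...) {
  cat(sprintf(
    "consensus policy: presence >= %s run(s); trim %d low + %d high; length/FA over %s runs\n",
    x$required_presence, x$n_trim_low, x$n_trim_high, x$length_fa_population))
  invisible(x)
}

resolve_presence <- function(policy, n_runs) {
  req <- if (identical(policy$required_presence, "all")) n_runs
  else as.integer(policy$required_presence)
  if (req > n_runs)
    stop_input("required presence (%d) exceeds number of runs (%d)", req, n_runs)
  if (policy$n_trim_low + policy$n_trim_high >= req)
    stop_input(
      "degenerate policy: trimming %d value(s) from a minimum of %d leaves nothing to average",
      policy$n_trim_low + policy$n_trim_high, req)
  req
}

#' Collect per-edge samples across repeated tractography runs
#'
#' Scans a list of per-run braingraphs (same subject, same node set) and
#' builds, for every edge occurring in at least one run, the vectors of
#' fiber counts, mean streamline lengths and mean FA values observed in the
#' runs containing the edge, ordered by run index.
#'
#' @param runs list of at least two `braingraph` objects with identical
#'   node sets.
#' @return an object of class `edge_sample_table`: parallel integer vectors
#'   `u`, `v`, a list column `samples` of per-edge data frames with columns
#'   `run`, `fiber_count`, `mean_length`, `mean_fa`, and attribute
#'   `n_runs`.
#' @export
collect_samples <- function(runs) {
  if (!is.list(runs) || length(runs) < 2)
    stop_input("need at least 2 runs, got %d", length(runs))
  ref <- runs[[1]]$nodes
  for (i in seq_along(runs)) {
    ni <- runs[[i]]$nodes
    if (!identical(ni$id, ref$id) || !identical(ni$label, ref$label))
      stop_input("run %d has a different node set than run 1", i)
  }
  nr <- vapply(runs, function(r) nrow(r$edges), 0L)
  if (sum(nr) == 0) {
    return(structure(list(u = integer(0), v = integer(0), samples = list()),
                     class = "edge_sample_table", n_runs = length(runs)))
  }
  u_v <- unlist(lapply(runs, function(r) r$edges$u), use.names = FALSE)
  v_v <- unlist(lapply(runs, function(r) r$edges$v), use.names = FALSE)
  fc_v <- unlist(lapply(runs, function(r) r$edges$fiber_count),
                 use.names = FALSE)
  ml_v <- unlist(lapply(runs, function(r) r$edges$mean_length),
                 use.names = FALSE)
  fa_v <- unlist(lapply(runs, function(r) r$edges$mean_fa), use.names = FALSE)
  run_v <- rep(seq_along(runs), nr)
  # deterministic order: by canonical pair, then run
  ord <- order(u_v, v_v, run_v)
  u_v <- u_v[ord]; v_v <- v_v[ord]; run_v <- run_v[ord]
  fc_v <- fc_v[ord]; ml_v <- ml_v[ord]; fa_v <- fa_v[ord]
  key <- paste(u_v, v_v, sep = ":")
  first <- !duplicated(key)
  idx <- split(seq_along(key), factor(key, levels = key[first]))
  samples <- lapply(idx, function(ii) {
    fast_df(list(run = run_v[ii], fiber_count = fc_v[ii],
                 mean_length = ml_v[ii], mean_fa = fa_v[ii]))
  })
  structure(
    list(u = u_v[first], v = v_v[first], samples = unname(samples)),
    class = "edge_sample_table", n_runs = length(runs)
  )
}

#' @export
print.edge_sample_table <- function(x, ...) {
  cat(sprintf("edge sample table: %d edge(s) over %d run(s)\n",
              length(x$u), attr(x, "n_runs")))
  invisible(x)
}

#' Number of runs each sampled edge appears in
#' @param table an `edge_sample_table`.
#' @return integer vector parallel to `table$u`.
#' @export
runs_present <- function(table) {
  vapply(table$samples, nrow, 0L)
}

#' Keep only edges meeting the consensus presence rule
#'
#' With the default policy an edge survives only if it was found in every
#' run; the surviving edge set is then exactly the intersection of the
#' per-run edge sets.
#'
#' @param table an `edge_sample_table` from [collect_samples()].
#' @param policy a [consensus_policy()].
#' @param n_runs total number of runs; defaults to the table's own count.
#' @return a filtered `edge_sample_table`.
#' @export
filter_consensus_edges <- function(table, policy = consensus_policy(),
                                   n_runs = attr(table, "n_runs")) {
  req <- resolve_presence(policy, n_runs)
  keep <- runs_present(table) >= req
  structure(
    list(u = table$u[keep], v = table$v[keep], samples = table$samples[keep]),
    class = "edge_sample_table", n_runs = n_runs
  )
}

#' Delete extremal values from a sample vector
#'
#' Removes `n_trim_low` occurrences of the smallest values and
#' `n_trim_high` of the largest (defaults: one of each, so 10 per-run fiber
#' counts leave 8). Ties are resolved deterministically: the occurrence
#' with the lowest index is dropped first on the low side, then, among the
#' remainder, the lowest index attaining the maximum.
#'
#' @param values numeric vector, longer than `n_trim_low + n_trim_high`.
#' @param n_trim_low,n_trim_high number of minima / maxima to delete.
#' @return list with `retained` (numeric vector) and `dropped_indices`
#'   (integer indices into `values`, minima first).
#' @examples
#' trim_extremes(1:10)$retained  # 2..9, mean 5.5
#' @export
trim_extremes <- function(values, n_trim_low = 1L, n_trim_high = 1L) {
  n_trim_low <- as.integer(n_trim_low)
  n_trim_high <- as.integer(n_trim_high)
  if (length(values) <= n_trim_low + n_trim_high)
    stop_input("need more than %d values to trim %d + %d, got %d",
               n_trim_low + n_trim_high, n_trim_low, n_trim_high,
               length(values))
  alive <- rep(TRUE, length(values))
  dropped <- integer(0)
  for (i in seq_len(n_trim_low)) {
    j <- which(alive)[which.min(values[alive])]
    alive[j] <- FALSE
    dropped <- c(dropped, j)
  }
  for (i in seq_len(n_trim_high)) {
    j <- which(alive)[which.max(values[alive])]
    alive[j] <- FALSE
    dropped <- c(dropped, j)
  }
  list(retained = values[alive], dropped_indices = dropped)
}

#' Aggregate one edge's samples into consensus weights
#'
#' Applies the min/max trim to the fiber-count vector and averages what
#' remains into the consensus fiber count. Streamline lengths and FA are
#' averaged over the same trim-surviving runs (default) or over all runs
#' the edge appears in, per the policy. Tied extremal counts are resolved
#' by lexicographic (count, length, FA, run) order so the result does not
#' depend on the order the runs are supplied in.
#'
#' @param entry one element of `edge_sample_table$samples`: a data frame
#'   with columns `run`, `fiber_count`, `mean_length`, `mean_fa`.
#' @param policy a [consensus_policy()].
#' @return named numeric vector with `fiber_count`, `mean_length`,
#'   `mean_fa`.
#' @export
aggregate_edge <- function(entry, policy = consensus_policy()) {
  n <- nrow(entry)
  lo <- policy$n_trim_low
  hi <- policy$n_trim_high
  if (n <= lo + hi)
    stop_input("edge observed in %d run(s); cannot trim %d value(s)", n, lo + hi)
  ord <- order(entry$fiber_count, entry$mean_length, entry$mean_fa, entry$run)
  keep <- ord[seq.int(lo + 1L, n - hi)]
  fc <- mean(entry$fiber_count[keep])
  if (policy$length_fa_population == "trimmed") {
    c(fiber_count = fc,
      mean_length = mean(entry$mean_length[keep]),
      mean_fa = mean(entry$mean_fa[keep]))
  } else {
    c(fiber_count = fc,
      mean_length = mean(entry$mean_length),
      mean_fa = mean(entry$mean_fa))
  }
}

#' Build a consensus braingraph from repeated tractography runs
#'
#' The robust aggregation pipeline: collect per-edge samples across runs,
#' keep only edges present in enough runs (all of them by default), delete
#' the extremal fiber counts of each surviving edge, and average the
#' remaining observations into the three consensus edge weights. With 10
#' runs and the default policy this is: intersect the 10 edge sets, drop
#' the minimum and maximum fiber count of each edge, and average the 8
#' remaining values — which is why consensus fiber counts are typically
#' non-integer.
#'
#' @param runs list of >= 2 per-run `braingraph` objects sharing a node set.
#' @param policy a [consensus_policy()].
#' @return a `braingraph` with the shared node set, consensus edges, and
#'   provenance recording the stage, run count and policy.
#' @examples
#' gt <- make_ground_truth(n_nodes = 6, edge_density = 0.5, seed = 7)
#' runs <- simulate_runs(gt, n_runs = 10, seed = 7)
#' cons <- build_consensus(runs)
#' print(cons)
#' @export
build_consensus <- function(runs, policy = consensus_policy()) {
  tab <- collect_samples(runs)
  resolve_presence(policy, length(runs))  # fail loudly on degenerate configs
  tab <- filter_consensus_edges(tab, policy, n_runs = length(runs))
  m <- length(tab$u)
  edges <- empty_edges()
  if (m) {
    w <- matrix(0, m, 3)
    for (i in seq_len(m)) w[i, ] <- aggregate_edge(tab$samples[[i]], policy)
    edges <- fast_df(list(u = tab$u, v = tab$v,
                          fiber_count = w[, 1], mean_length = w[, 2],
                          mean_fa = w[, 3]))
  }
  braingraph(
    runs[[1]]$nodes, edges,
    resolution_label = runs[[1]]$resolution_label,
    provenance = list(
      stage = "consensus",
      n_runs = length(runs),
      required_presence = policy$required_presence,
      n_trim_low = policy$n_trim_low,
      n_trim_high = policy$n_trim_high,
      length_fa_population = policy$length_fa_population
    )
  )
}
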