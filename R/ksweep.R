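#' Replicate mean, standard deviation and coefficient of variation
#'
#' The three summary statistics of the repetition analysis, applied to the
#' per-edge averaged fiber weights `w_i` of the replicate graphs: the
#' arithmetic mean `mu = (1/n) * sum(w_i)`, the Bessel-corrected sample
#' standard deviation `sigma = sqrt(sum((w_i - mu)^2) / (n - 1))`, and the
#' relative standard deviation (coefficient of variation)
#' `c_v = sigma / mu`.
#'
#' @param values numeric vector of replicate values (length >= 1 for the
#'   mean, >= 2 for the sd and c_v).
#' @return numeric scalar.
#' @examples
#' replicate_mean(1:10)  # 5.5
#' replicate_sd(1:10)    # sqrt(82.5 / 9)
#' relative_sd(1:10)     # their ratio
#' @export
replicate_mean <- function(values) {
  if (!length(values)) stop_input("cannot average an empty vector")
  sum(values) / length(values)
}

#' @rdname replicate_mean
#' @export
replicate_sd <- function(values) {
  n <- length(values)
  if (n < 2) stop_input("sample sd needs at least 2 values, got %d", n)
  mu <- replicate_mean(values)
  sqrt(sum((values - mu)^2) / (n - 1))
}

#' @rdname replicate_mean
#' @export
relative_sd <- function(values) {
  mu <- replicate_mean(values)
  if (mu == 0)
    stop_input("coefficient of variation undefined: mean is zero (consensus fiber means are >= 1, so this signals bad input)")
  replicate_sd(values) / mu
}

#' Mean deviation from the sample mean
#'
#' Numerically evaluates `mean(x - mean(x))`, which is identically zero in
#' exact arithmetic — the algebraic fact `E(X - E(X)) = 0` that makes
#' averaging repeated tractography runs increase reliability. The returned
#' residual should satisfy `|residual| <= 1e-9 * max(1, |mean(x)|)`; it is
#' a numerical-stability check, not an estimator.
#'
#' @param values non-empty numeric vector.
#' @return numeric scalar (the residual).
#' @export
expected_deviation_check <- function(values) {
  if (!length(values)) stop_input("empty vector")
  mu <- mean(values)
  mean(values - mu)
}

#' Average k tractography runs into one replicate graph
#'
#' Builds the k-run-averaged graph `G_k_i` of the repetition analysis: the
#' per-edge fiber weight is the mean fiber count over the k runs. Two
#' presence semantics are supported, since "averaging over the k runs" can
#' read either way: `"any"` (default) keeps every edge seen in at least
#' one run and counts the runs where it is absent as zero fibers; `"all"`
#' keeps only edges seen in every run. No trimming happens at this stage.
#' Lengths and FA are averaged over the runs where the edge is present.
#'
#' @param runs list of k >= 1 per-run `braingraph` objects (shared node
#'   set).
#' @param presence_rule `"any"` or `"all"`.
#' @return a `braingraph` whose fiber counts are k-run means.
#' @export
build_averaged_replicate <- function(runs, presence_rule = c("any", "all")) {
  presence_rule <- match.arg(presence_rule)
  if (!length(runs)) stop_input("need at least 1 run")
  k <- length(runs)
  if (k == 1) return(runs[[1]])
  tab <- collect_samples(runs)
  keep <- if (presence_rule == "all") runs_present(tab) == k
  else rep(TRUE, length(tab$u))
  m <- sum(keep)
  edges <- empty_edges()
  if (m) {
    samples <- tab$samples[keep]
    edges <- data.frame(
      u = tab$u[keep], v = tab$v[keep],
      # absences count as zero fibers under "any": divide by k, not by
      # the number of runs containing the edge
      fiber_count = vapply(samples, function(s) sum(s$fiber_count), 0) / k,
      mean_length = vapply(samples, function(s) mean(s$mean_length), 0),
      mean_fa = vapply(samples, function(s) mean(s$mean_fa), 0)
    )
  }
  braingraph(runs[[1]]$nodes, edges,
             resolution_label = runs[[1]]$resolution_label,
             provenance = list(stage = "averaged_replicate", k = k,
                               presence_rule = presence_rule))
}

## lower/upper quartiles as medians of the lower/upper half of the sorted
## data (median excluded when n is odd) — the "middle half of the data
## points" box convention
quartile_hinges <- function(x) {
  s <- sort(x)
  n <- length(s)
  h <- floor(n / 2)
  if (h == 0) return(c(q1 = s[1], q3 = s[n]))
  c(q1 = stats::median(s[seq_len(h)]),
    q3 = stats::median(s[seq.int(n - h + 1, n)]))
}

#' Repetition sweep of the edge-weight coefficient of variation
#'
#' For each candidate repetition count `k`, builds `n_replicates`
#' independent k-run-averaged replicate graphs, discards edges not present
#' in every replicate, and computes the per-edge relative standard
#' deviation (coefficient of variation) of the replicate fiber weights.
#' The per-k distribution of c_v over edges — median, quartiles, min, max
#' — quantifies how run-to-run variability shrinks as more runs are
#' averaged, the basis for choosing the repetition count.
#'
#' @param run_source a [ground_truth_model()] (runs are simulated), or a
#'   function `(n_runs, seed) -> list of braingraphs`.
#' @param k_values integer vector of candidate repetition counts
#'   (default 1:50).
#' @param n_replicates replicate graphs per k (default 10).
#' @param seed master seed; every (k, replicate, run) stream is derived
#'   from it deterministically.
#' @param presence_rule passed to [build_averaged_replicate()].
#' @return an object of class `ksweep_result` with `per_edge`
#'   (data frame: `k`, `u`, `v`, `mean_w`, `cv`), `summary` (data frame:
#'   `k`, `median`, `q1`, `q3`, `min`, `max`, `n_edges`) and the
#'   configuration; has `print`, `summary` and `plot` methods.
#' @examples
#' gt <- make_ground_truth(n_nodes = 5, edge_density = 0.6, seed = 3)
#' sw <- k_sweep(gt, k_values = c(1, 4, 8), n_replicates = 6, seed = 3)
#' summary(sw)
#' @export
k_sweep <- function(run_source, k_values = 1:50, n_replicates = 10L,
                    seed = 1L, presence_rule = c("any", "all")) {
  presence_rule <- match.arg(presence_rule)
  k_values <- sort(unique(as.integer(k_values)))
  if (!length(k_values) || any(k_values < 1))
    stop_input("k_values must be positive integers")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2) stop_input("n_replicates must be >= 2")
  get_runs <- if (inherits(run_source, "ground_truth_model")) {
    function(n, s) simulate_runs(run_source, n_runs = n, seed = s)
  } else if (is.function(run_source)) {
    run_source
  } else {
    stop_input("run_source must be a ground_truth_model or a function(n_runs, seed)")
  }

  per_edge <- vector("list", length(k_values))
  summ <- vector("list", length(k_values))
  for (ki in seq_along(k_values)) {
    k <- k_values[ki]
    reps <- lapply(seq_len(n_replicates), function(i) {
      runs <- get_runs(k, derive_seed(seed, k, i))
      build_averaged_replicate(runs, presence_rule = presence_rule)
    })
    # edges present in all replicate graphs
    keys <- lapply(reps, function(g) edge_keys(g$edges))
    common <- Reduce(intersect, keys)
    if (length(common)) {
      w <- vapply(seq_along(reps), function(i) {
        e <- reps[[i]]$edges
        e$fiber_count[match(common, keys[[i]])]
      }, numeric(length(common)))
      w <- matrix(w, nrow = length(common))
      uv <- do.call(rbind, strsplit(common, ":", fixed = TRUE))
      mean_w <- apply(w, 1, replicate_mean)
      cv <- vapply(seq_len(nrow(w)), function(j) relative_sd(w[j, ]), 0)
      ord <- order(as.integer(uv[, 1]), as.integer(uv[, 2]))
      per_edge[[ki]] <- data.frame(
        k = k, u = as.integer(uv[ord, 1]), v = as.integer(uv[ord, 2]),
        mean_w = mean_w[ord], cv = cv[ord])
      hq <- quartile_hinges(cv)
      summ[[ki]] <- data.frame(
        k = k, median = stats::median(cv), q1 = hq[["q1"]], q3 = hq[["q3"]],
        min = min(cv), max = max(cv), n_edges = length(cv))
    } else {
      summ[[ki]] <- data.frame(k = k, median = NA_real_, q1 = NA_real_,
                               q3 = NA_real_, min = NA_real_, max = NA_real_,
                               n_edges = 0L)
    }
  }
  structure(
    list(per_edge = do.call(rbind, per_edge),
         summary = do.call(rbind, summ),
         k_values = k_values, n_replicates = n_replicates,
         presence_rule = presence_rule, seed = as.integer(seed)),
    class = "ksweep_result"
  )
}

#' @export
print.ksweep_result <- function(x, ...) {
  cat(sprintf(
    "repetition sweep: k in {%s}, %d replicates per k, presence rule '%s'\n",
    paste(x$k_values, collapse = ", "), x$n_replicates, x$presence_rule))
  cat(sprintf("  median c_v: %.4g (k = %d) -> %.4g (k = %d)\n",
              x$summary$median[1], x$summary$k[1],
              x$summary$median[nrow(x$summary)],
              x$summary$k[nrow(x$summary)]))
  invisible(x)
}

#' @export
summary.ksweep_result <- function(object, ...) {
  object$summary
}

#' Per-edge coefficient-of-variation curve over k
#'
#' Extracts one edge's c_v as a function of the repetition count — the
#' single-edge convergence curve.
#'
#' @param result a `ksweep_result`.
#' @param u,v node ids of the edge.
#' @return data frame with columns `k` and `cv`.
#' @export
cv_curve <- function(result, u, v) {
  lo <- min(u, v); hi <- max(u, v)
  pe <- result$per_edge
  out <- pe[pe$u == lo & pe$v == hi, c("k", "cv")]
  if (!nrow(out)) stop_input("edge %d:%d not present in the sweep result", lo, hi)
  rownames(out) <- NULL
  out
}

#' Plot a repetition sweep
#'
#' Box-style display of the per-edge coefficient-of-variation distribution
#' against k: boxes span the middle half of the edges (lower to upper
#' quartile), the red segment marks the median, and whiskers the full
#' spread.
#'
#' @param x a `ksweep_result`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ksweep_result <- function(x, ...) {
  s <- x$summary[!is.na(x$summary$median), ]
  if (!nrow(s)) stop_input("nothing to plot: no edge survived any k")
  bw <- if (nrow(s) > 1) min(diff(sort(s$k))) * 0.35 else 0.35
  graphics::plot(NA, xlim = range(s$k) + c(-1, 1) * bw,
                 ylim = c(0, max(s$max)), xlab = "repetitions k",
                 ylab = "relative standard deviation of edge weight", ...)
  graphics::segments(s$k, s$min, s$k, s$max, col = "grey40")
  graphics::rect(s$k - bw, s$q1, s$k + bw, s$q3, col = "grey85",
                 border = "grey30")
  graphics::segments(s$k - bw, s$median, s$k + bw, s$median, col = "red",
                     lwd = 2)
  invisible(x)
}

#' Recommend a repetition count from a sweep
#'
#' Operationalizes the "good trade-off between deviation and practical
#' computability" choice: returns the smallest sampled k after which the
#' relative decrease of the median c_v to the next sampled k falls below
#' `rel_improvement_tol`. Monte-Carlo jitter in the median sequence is
#' damped by a running median of width 3 (endpoints kept) before applying
#' the rule. If no k qualifies, the largest sampled k is returned with a
#' warning.
#'
#' @param result a `ksweep_result` covering >= 2 values of k.
#' @param rel_improvement_tol relative-improvement threshold (default
#'   0.05).
#' @return integer k.
#' @export
recommend_k <- function(result, rel_improvement_tol = 0.05) {
  s <- result$summary[!is.na(result$summary$median), ]
  if (nrow(s) < 2) stop_input("need at least 2 sampled k values")
  s <- s[order(s$k), ]
  med <- s$median
  if (length(med) >= 3)
    med <- as.numeric(stats::runmed(med, 3, endrule = "keep"))
  drop_rel <- ifelse(med[-length(med)] > 0,
                     (med[-length(med)] - med[-1]) / med[-length(med)],
                     0)
  ok <- which(drop_rel < rel_improvement_tol)
  if (length(ok)) return(s$k[ok[1]])
  warning("median c_v still improving at the largest sampled k; returning it")
  s$k[nrow(s)]
}
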