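## exact 32-bit helpers on doubles (values < 2^32; 16-bit limb arithmetic)
bitxor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

mult32 <- function(a, b) {
  a_hi <- a %/% 65536
  a_lo <- a %% 65536
  (((a_hi * b) %% 65536) * 65536 + a_lo * b) %% 4294967296
}

## Deterministic substream seeds: hash a master seed plus stream indices
## into a 31-bit integer with an avalanche finalizer, so that adjacent
## (k, replicate, run) indices yield unrelated RNG seeds. Adjacent raw
## integer seeds must be avoided: their first Mersenne-Twister draws are
## noticeably correlated, which biases joint-presence probabilities.
derive_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  h <- 0
  for (v in idx) {
    h <- (h + (as.numeric(v) %% 4294967296) + 2654435769) %% 4294967296
    h <- bitxor32(h, h %/% 65536)
    h <- mult32(h, 2246822519)
    h <- bitxor32(h, h %/% 8192)
    h <- mult32(h, 3266489917)
    h <- bitxor32(h, h %/% 65536)
  }
  as.integer(h %% 2147483647)
}

#' Default parameter ranges for the simulated tract model
#'
#' Ranges used by [make_ground_truth()] when drawing per-edge parameters.
#' Detection probabilities are high (most anatomical connections are found
#' in most runs); fiber-count rates span weak to strong bundles; streamline
#' lengths span short association to long projection tracts; FA means sit
#' in the usual white-matter range; `length_sd_frac` is the per-run length
#' standard deviation as a fraction of the mean.
#'
#' @return named list of length-2 numeric ranges.
#' @export
default_parameter_ranges <- function() {
  list(
    detection_p = c(0.7, 1.0),
    count_rate = c(5, 150),
    length_mean = c(20, 120),
    length_sd_frac = c(0.05, 0.2),
    fa_mean = c(0.25, 0.6),
    fa_concentration = c(50, 200)
  )
}

#' Construct a ground-truth tract model
#'
#' The latent model behind the simulator: a fixed node set and a set of
#' true connections, each with a per-run detection probability `p`, a
#' fiber-count rate `lambda` (counts are zero-truncated Poisson, since an
#' edge exists in a run only when at least one streamline is found), a
#' streamline-length law (positive-truncated normal) and an FA law (beta,
#' parameterized by mean and concentration, so FA stays in \[0, 1\] by
#' construction).
#'
#' @param nodes node data frame as in [braingraph()].
#' @param edges data frame with columns `u`, `v`, `detection_p`,
#'   `count_rate`, `length_mean`, `length_sd`, `fa_mean`,
#'   `fa_concentration`.
#' @param noise `"stochastic"` (default) or `"none"`; with `"none"` every
#'   included edge reports the deterministic values `max(1, round(rate))`,
#'   `length_mean` and `fa_mean`.
#' @param spurious_rate probability that any non-true node pair appears as
#'   a false-positive edge in a run (default 0; stress-testing knob).
#' @return an object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(nodes, edges, noise = c("stochastic", "none"),
                               spurious_rate = 0) {
  noise <- match.arg(noise)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("u", "v", "detection_p", "count_rate", "length_mean",
            "length_sd", "fa_mean", "fa_concentration")
  if (!all(need %in% names(edges)))
    stop_input("model edges missing column(s): %s",
               paste(setdiff(need, names(edges)), collapse = ", "))
  edges <- edges[need]
  if (nrow(edges)) {
    swap <- edges$u > edges$v
    tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
    if (any(edges$u == edges$v)) stop_input("self-loop in true edge set")
    if (any(edges$detection_p <= 0 | edges$detection_p > 1))
      stop_input("detection probabilities must lie in (0, 1]")
    if (any(edges$count_rate <= 0) || any(edges$fa_concentration <= 0))
      stop_input("rates and concentrations must be positive")
    if (any(edges$fa_mean <= 0 | edges$fa_mean >= 1))
      stop_input("fa_mean must lie in (0, 1)")
    if (any(edges$length_mean <= 0) || any(edges$length_sd < 0))
      stop_input("length parameters must be positive")
  }
  if (spurious_rate < 0 || spurious_rate >= 1)
    stop_input("spurious_rate must lie in [0, 1)")
  structure(list(nodes = nodes, edges = edges, noise = noise,
                 spurious_rate = spurious_rate),
            class = "ground_truth_model")
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf(
    "ground-truth tract model: %d nodes, %d true edges, %s noise%s\n",
    nrow(x$nodes), nrow(x$edges), x$noise,
    if (x$spurious_rate > 0)
      sprintf(", spurious rate %.3g", x$spurious_rate) else ""))
  invisible(x)
}

#' Generate a random ground-truth tract model
#'
#' Draws `floor(edge_density * choose(n_nodes, 2))` true connections
#' uniformly among node pairs and samples their parameters uniformly from
#' `parameter_ranges`. Node labels are synthetic region names with
#' alternating hemispheres and uniform random positions in a 100 mm box.
#' Fully reproducible from `seed`.
#'
#' @param n_nodes number of regions (>= 2).
#' @param edge_density fraction of node pairs that are true connections,
#'   in (0, 1].
#' @param parameter_ranges see [default_parameter_ranges()].
#' @param seed integer seed.
#' @param noise,spurious_rate passed to [ground_truth_model()].
#' @return a `ground_truth_model`.
#' @export
make_ground_truth <- function(n_nodes, edge_density = 0.3,
                              parameter_ranges = default_parameter_ranges(),
                              seed = 1L, noise = "stochastic",
                              spurious_rate = 0) {
  if (n_nodes < 2) stop_input("need at least 2 nodes")
  if (edge_density <= 0 || edge_density > 1)
    stop_input("edge_density must lie in (0, 1]")
  n_pairs <- choose(n_nodes, 2)
  m <- floor(edge_density * n_pairs)
  if (m < 1) stop_input("edge_density %g on %d nodes yields no edges",
                        edge_density, n_nodes)
  set.seed(derive_seed(seed, 101L))
  hemi <- rep(c("left", "right"), length.out = n_nodes)
  nodes <- data.frame(
    id = seq_len(n_nodes),
    label = sprintf("%s.roi%03d", ifelse(hemi == "left", "lh", "rh"),
                    seq_len(n_nodes)),
    hemisphere = hemi,
    x = stats::runif(n_nodes, 0, 100),
    y = stats::runif(n_nodes, 0, 100),
    z = stats::runif(n_nodes, 0, 100),
    stringsAsFactors = FALSE
  )
  pairs <- utils::combn(n_nodes, 2)
  pick <- sort(sample.int(ncol(pairs), m))
  pr <- parameter_ranges
  runi <- function(rg, n) stats::runif(n, rg[1], rg[2])
  lm_ <- runi(pr$length_mean, m)
  # a noiseless model means every run is identical, so detection is certain
  det_p <- if (identical(noise, "none")) rep(1, m) else runi(pr$detection_p, m)
  edges <- data.frame(
    u = pairs[1, pick], v = pairs[2, pick],
    detection_p = det_p,
    count_rate = runi(pr$count_rate, m),
    length_mean = lm_,
    length_sd = lm_ * runi(pr$length_sd_frac, m),
    fa_mean = runi(pr$fa_mean, m),
    fa_concentration = runi(pr$fa_concentration, m)
  )
  ground_truth_model(nodes, edges, noise = noise,
                     spurious_rate = spurious_rate)
}

## zero-truncated Poisson sampler (inverse-cdf on the truncated tail)
rztpois <- function(n, lambda) {
  p0 <- stats::ppois(0, lambda)
  stats::qpois(stats::runif(n, p0, 1), lambda)
}

#' Simulate one probabilistic-tractography run
#'
#' Each true edge is detected independently with its detection probability;
#' detected edges report a zero-truncated Poisson fiber count (so every
#' reported edge has at least one streamline, matching the edge-definition
#' rule), a positive-truncated normal mean streamline length, and a
#' beta-distributed mean FA. With model noise `"none"` the reported values
#' are the deterministic model values.
#'
#' @param model a [ground_truth_model()].
#' @param run_seed integer seed for this run.
#' @return a per-run `braingraph` (integer fiber counts >= 1).
#' @export
simulate_run <- function(model, run_seed = 1L) {
  set.seed(as.integer(run_seed))
  te <- model$edges
  m <- nrow(te)
  present <- if (m) stats::runif(m) < te$detection_p else logical(0)
  edges <- empty_edges()
  if (any(present)) {
    e <- te[present, , drop = FALSE]
    k <- nrow(e)
    if (model$noise == "none") {
      fc <- pmax(1, round(e$count_rate))
      ml <- e$length_mean
      fa <- e$fa_mean
    } else {
      fc <- rztpois(k, e$count_rate)
      ml <- stats::rnorm(k, e$length_mean, e$length_sd)
      bad <- which(ml <= 0)
      while (length(bad)) {  # positive truncation by redraw
        ml[bad] <- stats::rnorm(length(bad), e$length_mean[bad],
                                e$length_sd[bad])
        bad <- bad[ml[bad] <= 0]
      }
      fa <- stats::rbeta(k, e$fa_mean * e$fa_concentration,
                         (1 - e$fa_mean) * e$fa_concentration)
      fa <- pmin(pmax(fa, 1e-6), 1 - 1e-6)
    }
    edges <- fast_df(list(u = e$u, v = e$v, fiber_count = as.numeric(fc),
                          mean_length = ml, mean_fa = fa))
  }
  if (model$spurious_rate > 0) {
    n <- nrow(model$nodes)
    pairs <- utils::combn(n, 2)
    keyt <- paste(model$edges$u, model$edges$v, sep = ":")
    keya <- paste(pairs[1, ], pairs[2, ], sep = ":")
    cand <- which(!(keya %in% keyt))
    hit <- cand[stats::runif(length(cand)) < model$spurious_rate]
    if (length(hit)) {
      sp <- data.frame(u = pairs[1, hit], v = pairs[2, hit],
                       fiber_count = rztpois(length(hit), 1),
                       mean_length = abs(stats::rnorm(length(hit), 50, 5)),
                       mean_fa = stats::rbeta(length(hit), 0.3 * 100,
                                              0.7 * 100))
      edges <- rbind(edges, sp)
    }
  }
  braingraph(model$nodes, edges,
             resolution_label = "native",
             provenance = list(stage = "run", run_seed = as.integer(run_seed)))
}

#' Simulate repeated tractography runs
#'
#' Run `i` is reproducible from `(seed, i)` alone; runs are mutually
#' independent streams.
#'
#' @param model a [ground_truth_model()].
#' @param n_runs number of runs (>= 1).
#' @param seed master integer seed.
#' @return list of `n_runs` per-run `braingraph` objects.
#' @export
simulate_runs <- function(model, n_runs = 10L, seed = 1L) {
  if (n_runs < 1) stop_input("n_runs must be >= 1")
  lapply(seq_len(n_runs), function(i) {
    g <- simulate_run(model, derive_seed(seed, 7L, i))
    g$provenance$run <- i
    g
  })
}

#' Serialize / restore a ground-truth model as JSON
#'
#' @param model a `ground_truth_model`.
#' @param path output / input file path.
#' @return `path` invisibly / the restored model.
#' @export
write_ground_truth <- function(model, path) {
  jsonlite::write_json(
    list(nodes = model$nodes, edges = model$edges, noise = model$noise,
         spurious_rate = model$spurious_rate),
    path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ground_truth_model(x$nodes, x$edges, noise = x$noise,
                     spurious_rate = x$spurious_rate)
}
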