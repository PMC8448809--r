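#' @keywords internal
"_PACKAGE"

## Classed error used for all input/validation failures so callers (and the
## CLI) can distinguish bad input (exit 2) from genuine bugs (exit 1).
stop_input <- function(msg, ..., class = "braincons_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_input_error <- function(e) inherits(e, "braincons_error")

## minimal data.frame builder for hot paths (no name deparsing, no checks;
## columns must already be equal-length atomic vectors)
fast_df <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1]])))
}

empty_nodes <- function() {
  data.frame(
    id = integer(0), label = character(0), hemisphere = character(0),
    x = numeric(0), y = numeric(0), z = numeric(0),
    stringsAsFactors = FALSE
  )
}

empty_edges <- function() {
  fast_df(list(
    u = integer(0), v = integer(0),
    fiber_count = numeric(0), mean_length = numeric(0), mean_fa = numeric(0)
  ))
}

#' Construct a braingraph
#'
#' A braingraph is an undirected graph whose vertices are anatomically
#' labeled parcellation regions and whose edges record discovered
#' white-matter connections between regions, weighted by the number of
#' streamlines (fibers), the mean streamline length in mm, and the mean
#' fractional anisotropy (FA) of the streamlines.
#'
#' Edge endpoints are stored canonically with the smaller node id first, so
#' each unordered region pair appears at most once. Self-loops are rejected.
#'
#' @param nodes data frame with columns `id` (positive integer, unique),
#'   `label` (non-empty character), `hemisphere` (`"left"`, `"right"` or
#'   `"none"`), and numeric coordinates `x`, `y`, `z`.
#' @param edges data frame with columns `u`, `v` (node ids), `fiber_count`
#'   (positive real; integer in single tractography runs, typically
#'   non-integer after averaging), `mean_length` (positive, mm) and
#'   `mean_fa` (in \[0, 1\]).
#' @param resolution_label character scalar naming the parcellation level.
#' @param provenance named list of free-form metadata (subject id, stage,
#'   number of runs, ...).
#' @return An object of class `braingraph`.
#' @examples
#' g <- braingraph(
#'   nodes = data.frame(
#'     id = 1:2, label = c("lh.a", "rh.a"),
#'     hemisphere = c("left", "right"), x = c(0, 1), y = 0, z = 0
#'   ),
#'   edges = data.frame(
#'     u = 1L, v = 2L, fiber_count = 12, mean_length = 43.5, mean_fa = 0.41
#'   )
#' )
#' print(g)
#' @export
braingraph <- function(nodes, edges = empty_edges(),
                       resolution_label = "native", provenance = list()) {
  if (!is.data.frame(nodes)) nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!is.data.frame(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need_n <- c("id", "label", "hemisphere", "x", "y", "z")
  need_e <- c("u", "v", "fiber_count", "mean_length", "mean_fa")
  if (!all(need_n %in% names(nodes)))
    stop_input("nodes is missing column(s): %s",
               paste(setdiff(need_n, names(nodes)), collapse = ", "))
  if (!all(need_e %in% names(edges)))
    stop_input("edges is missing column(s): %s",
               paste(setdiff(need_e, names(edges)), collapse = ", "))
  if (!identical(names(nodes), need_n)) nodes <- nodes[need_n]
  if (!identical(names(edges), need_e)) edges <- edges[need_e]
  nodes$id <- as.integer(nodes$id)
  nodes$label <- as.character(nodes$label)
  nodes$hemisphere <- as.character(nodes$hemisphere)
  edges$u <- as.integer(edges$u)
  edges$v <- as.integer(edges$v)

  # canonical endpoint order: smaller id first
  if (nrow(edges)) {
    swap <- edges$u > edges$v
    if (any(swap)) {
      tmp <- edges$u[swap]
      edges$u[swap] <- edges$v[swap]
      edges$v[swap] <- tmp
    }
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL

  g <- structure(
    list(nodes = nodes, edges = edges,
         resolution_label = as.character(resolution_label)[1],
         provenance = provenance),
    class = "braingraph"
  )
  validate_braingraph(g)
  g
}

#' Validate braingraph invariants
#'
#' Checks node-id uniqueness, non-empty labels, hemisphere values, absence of
#' self-loops and duplicate edges, endpoint existence, positive fiber counts
#' and lengths, and FA within \[0, 1\]. Called by [braingraph()]; exported for
#' use after manual manipulation of the components.
#'
#' @param g a `braingraph`.
#' @param per_run logical; if `TRUE` additionally require integer fiber
#'   counts >= 1, the invariant of a single tractography run (an edge exists
#'   only if at least one streamline was found).
#' @return `g`, invisibly.
#' @export
validate_braingraph <- function(g, per_run = FALSE) {
  n <- g$nodes
  e <- g$edges
  if (anyDuplicated(n$id))
    stop_input("duplicate node id(s): %s",
               paste(unique(n$id[duplicated(n$id)]), collapse = ", "))
  if (any(is.na(n$id)) || any(n$id < 1L))
    stop_input("node ids must be positive integers")
  if (any(is.na(n$label)) || any(!nzchar(n$label)))
    stop_input("anatomical labels must be non-empty")
  if (any(!n$hemisphere %in% c("left", "right", "none")))
    stop_input("hemisphere must be one of 'left', 'right', 'none'")
  if (any(!is.finite(n$x)) || any(!is.finite(n$y)) || any(!is.finite(n$z)))
    stop_input("node positions must be finite")
  if (nrow(e)) {
    if (any(e$u == e$v))
      stop_input("self-loop edge at node(s): %s",
                 paste(unique(e$u[e$u == e$v]), collapse = ", "))
    key <- paste(e$u, e$v, sep = ":")
    if (anyDuplicated(key))
      stop_input("duplicate edge(s): %s",
                 paste(unique(key[duplicated(key)]), collapse = ", "))
    known <- c(e$u, e$v) %in% n$id
    if (!all(known))
      stop_input("edge endpoint(s) not among node ids: %s",
                 paste(unique(c(e$u, e$v)[!known]), collapse = ", "))
    if (any(!is.finite(e$fiber_count)) || any(e$fiber_count <= 0))
      stop_input("fiber_count must be positive and finite")
    if (any(!is.finite(e$mean_length)) || any(e$mean_length <= 0))
      stop_input("mean_length must be positive and finite")
    if (any(!is.finite(e$mean_fa)) || any(e$mean_fa < 0) || any(e$mean_fa > 1))
      stop_input("mean_fa must lie in [0, 1]")
    if (per_run && any(e$fiber_count < 1 | e$fiber_count != round(e$fiber_count)))
      stop_input("per-run fiber counts must be integers >= 1")
  }
  invisible(g)
}

edge_keys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  paste(edges$u, edges$v, sep = ":")
}

#' Number of nodes / edges of a braingraph
#' @param g a `braingraph`.
#' @return integer count.
#' @export
n_nodes <- function(g) nrow(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' Total fiber mass of a braingraph
#'
#' Sum of fiber-count weights over all edges; the conserved quantity of
#' vertex contraction.
#' @param g a `braingraph`.
#' @return numeric scalar.
#' @export
fiber_mass <- function(g) as.numeric(sum(g$edges$fiber_count))

#' Compare two braingraphs for equality
#'
#' Graphs are equal when they have the same node table (ids, labels,
#' hemispheres, positions) and the same canonical edge set with all three
#' weights agreeing within `tol` (absolute or relative, whichever is looser).
#'
#' @param a,b `braingraph` objects.
#' @param tol numeric tolerance on weights and positions; `0` demands exact
#'   equality.
#' @return logical scalar.
#' @export
braingraph_equal <- function(a, b, tol = 0) {
  num_eq <- function(x, y) {
    if (length(x) != length(y)) return(FALSE)
    if (!length(x)) return(TRUE)
    d <- abs(x - y)
    all(d <= tol | d <= tol * pmax(abs(x), abs(y)))
  }
  if (n_nodes(a) != n_nodes(b) || n_edges(a) != n_edges(b)) return(FALSE)
  if (!identical(a$nodes$id, b$nodes$id)) return(FALSE)
  if (!identical(a$nodes$label, b$nodes$label)) return(FALSE)
  if (!identical(a$nodes$hemisphere, b$nodes$hemisphere)) return(FALSE)
  if (!num_eq(a$nodes$x, b$nodes$x) || !num_eq(a$nodes$y, b$nodes$y) ||
      !num_eq(a$nodes$z, b$nodes$z)) return(FALSE)
  if (!identical(a$edges$u, b$edges$u) || !identical(a$edges$v, b$edges$v))
    return(FALSE)
  num_eq(a$edges$fiber_count, b$edges$fiber_count) &&
    num_eq(a$edges$mean_length, b$edges$mean_length) &&
    num_eq(a$edges$mean_fa, b$edges$mean_fa)
}

#' @export
print.braingraph <- function(x, ...) {
  cat(sprintf("braingraph: %d nodes, %d edges (resolution '%s')\n",
              n_nodes(x), n_edges(x), x$resolution_label))
  if (n_edges(x)) {
    cat(sprintf("  fiber mass %.6g; fiber count range [%.6g, %.6g]\n",
                fiber_mass(x), min(x$edges$fiber_count),
                max(x$edges$fiber_count)))
  }
  if (length(x$provenance)) {
    cat("  provenance:",
        paste(names(x$provenance),
              vapply(x$provenance, function(p) paste(format(p), collapse = ","),
                     character(1)),
              sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
summary.braingraph <- function(object, ...) {
  e <- object$edges
  deg <- tabulate(match(c(e$u, e$v), object$nodes$id), nbins = n_nodes(object))
  out <- list(
    n_nodes = n_nodes(object),
    n_edges = n_edges(object),
    resolution_label = object$resolution_label,
    fiber_mass = fiber_mass(object),
    degree = summary(deg),
    fiber_count = if (nrow(e)) summary(e$fiber_count) else NULL,
    mean_length = if (nrow(e)) summary(e$mean_length) else NULL,
    mean_fa = if (nrow(e)) summary(e$mean_fa) else NULL
  )
  class(out) <- "summary.braingraph"
  out
}

#' @export
print.summary.braingraph <- function(x, ...) {
  cat(sprintf("braingraph at resolution '%s': %d nodes, %d edges, fiber mass %.6g\n",
              x$resolution_label, x$n_nodes, x$n_edges, x$fiber_mass))
  cat("degree:\n"); print(x$degree)
  if (!is.null(x$fiber_count)) {
    cat("fiber count:\n"); print(x$fiber_count)
    cat("mean length (mm):\n"); print(x$mean_length)
    cat("mean FA:\n"); print(x$mean_fa)
  }
  invisible(x)
}

#' Plot a braingraph
#'
#' Draws nodes at their (x, y) scanner coordinates and edges with line width
#' proportional to the fiber count.
#'
#' @param x a `braingraph`.
#' @param max_lwd maximum edge line width.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.braingraph <- function(x, max_lwd = 4, ...) {
  n <- x$nodes
  e <- x$edges
  graphics::plot(n$x, n$y, pch = 19, cex = 0.8, xlab = "x", ylab = "y",
                 main = sprintf("braingraph (%s)", x$resolution_label), ...)
  if (nrow(e)) {
    w <- e$fiber_count / max(e$fiber_count) * max_lwd
    iu <- match(e$u, n$id); iv <- match(e$v, n$id)
    graphics::segments(n$x[iu], n$y[iu], n$x[iv], n$y[iv],
                       lwd = pmax(w, 0.3), col = grDevices::grey(0.4, 0.6))
    graphics::points(n$x, n$y, pch = 19, cex = 0.8)
  }
  invisible(x)
}
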