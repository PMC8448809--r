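#' Contract a braingraph to a coarser parcellation level
#'
#' Merges every group of fine regions sharing a coarse label into one
#' vertex. Fiber counts of the multiple fine edges joining two coarse
#' vertices are summed; their mean streamline lengths and mean FA are
#' combined as fiber-count-weighted means (so the coarse value stays
#' within the range of the merged fine values). Fine edges that fall
#' inside a single coarse vertex become self-loops and are dropped; their
#' fiber mass is reported, never silently lost, so that
#' `mass_after + self_loop_mass_dropped == mass_before`.
#'
#' Coarse node positions are the unweighted centroids of the constituent
#' fine-node positions; the hemisphere is kept when all constituents agree
#' and set to `"none"` otherwise.
#'
#' @param graph a `braingraph` whose node labels all occur at some level
#'   of `hierarchy` (the finest, unless `source_level` says otherwise).
#' @param hierarchy a [parcellation_hierarchy()].
#' @param target_level name of the level to contract to.
#' @param source_level level the graph's labels live at; `NULL` (default)
#'   finds the finest level containing every graph label.
#' @return list with `graph` (the contracted `braingraph`) and `report`
#'   (a `contraction_report` with node/edge/fiber-mass bookkeeping).
#' @export
contract_graph <- function(graph, hierarchy, target_level,
                           source_level = NULL) {
  if (is.null(source_level)) {
    for (lv in hierarchy$levels) {
      if (all(graph$nodes$label %in% hierarchy$table[[lv]])) {
        source_level <- lv
        break
      }
    }
    if (is.null(source_level))
      stop_input("graph labels do not all occur at any hierarchy level")
  }
  if (!target_level %in% hierarchy$levels)
    stop_input("unknown level '%s'", target_level)

  mk_report <- function(g2, dropped) {
    structure(list(
      source_level = source_level, target_level = target_level,
      n_nodes_before = n_nodes(graph), n_nodes_after = n_nodes(g2),
      n_edges_before = n_edges(graph), n_edges_after = n_edges(g2),
      fiber_mass_before = fiber_mass(graph), fiber_mass_after = fiber_mass(g2),
      self_loop_mass_dropped = dropped
    ), class = "contraction_report")
  }

  if (identical(target_level, source_level)) {
    return(list(graph = graph, report = mk_report(graph, 0)))
  }
  map <- level_map(hierarchy, source_level, target_level)
  unknown <- setdiff(graph$nodes$label, names(map))
  if (length(unknown))
    stop_input("label(s) not mapped at level '%s': %s", source_level,
               paste(utils::head(unknown, 5), collapse = ", "))

  fine <- graph$nodes
  coarse_lab <- unname(map[fine$label])
  groups <- sort(unique(coarse_lab))
  cid <- match(coarse_lab, groups)  # coarse id per fine node

  nodes <- data.frame(
    id = seq_along(groups),
    label = groups,
    hemisphere = vapply(seq_along(groups), function(k) {
      h <- unique(fine$hemisphere[cid == k])
      if (length(h) == 1) h else "none"
    }, ""),
    x = vapply(seq_along(groups), function(k) mean(fine$x[cid == k]), 0),
    y = vapply(seq_along(groups), function(k) mean(fine$y[cid == k]), 0),
    z = vapply(seq_along(groups), function(k) mean(fine$z[cid == k]), 0),
    stringsAsFactors = FALSE
  )

  e <- graph$edges
  dropped <- 0
  edges <- empty_edges()
  if (nrow(e)) {
    cu <- cid[match(e$u, fine$id)]
    cv <- cid[match(e$v, fine$id)]
    lo <- pmin(cu, cv)
    hi <- pmax(cu, cv)
    self <- lo == hi
    dropped <- sum(e$fiber_count[self])
    if (any(!self)) {
      lo <- lo[!self]; hi <- hi[!self]
      fc <- e$fiber_count[!self]
      ml <- e$mean_length[!self]
      fa <- e$mean_fa[!self]
      key <- factor(paste(lo, hi, sep = ":"),
                    levels = unique(paste(lo[order(lo, hi)],
                                          hi[order(lo, hi)], sep = ":")))
      sum_fc <- tapply(fc, key, sum)
      sum_l <- tapply(fc * ml, key, sum)
      sum_f <- tapply(fc * fa, key, sum)
      pair <- do.call(rbind, strsplit(names(sum_fc), ":", fixed = TRUE))
      edges <- data.frame(
        u = as.integer(pair[, 1]), v = as.integer(pair[, 2]),
        fiber_count = as.numeric(sum_fc),
        mean_length = as.numeric(sum_l / sum_fc),
        mean_fa = as.numeric(sum_f / sum_fc)
      )
    }
  }

  prov <- graph$provenance
  prov$contracted_from <- source_level
  g2 <- braingraph(nodes, edges, resolution_label = target_level,
                   provenance = prov)
  list(graph = g2, report = mk_report(g2, dropped))
}

#' Contract a braingraph to every level of a hierarchy
#'
#' @param graph a `braingraph` at the hierarchy's finest level.
#' @param hierarchy a [parcellation_hierarchy()].
#' @return named list of `braingraph` objects, one per level (finest
#'   first); the finest entry is `graph` itself. Contraction reports are
#'   attached as attribute `"reports"`.
#' @export
contract_all_levels <- function(graph, hierarchy) {
  out <- vector("list", length(hierarchy$levels))
  names(out) <- hierarchy$levels
  reports <- list()
  for (lv in hierarchy$levels) {
    if (lv == hierarchy$levels[1]) {
      out[[lv]] <- graph
    } else {
      res <- contract_graph(graph, hierarchy, lv,
                            source_level = hierarchy$levels[1])
      out[[lv]] <- res$graph
      reports[[lv]] <- res$report
    }
  }
  attr(out, "reports") <- reports
  out
}

#' @export
print.contraction_report <- function(x, ...) {
  cat(sprintf("contraction %s -> %s\n", x$source_level, x$target_level))
  cat(sprintf("  nodes %d -> %d; edges %d -> %d\n",
              x$n_nodes_before, x$n_nodes_after,
              x$n_edges_before, x$n_edges_after))
  cat(sprintf("  fiber mass %.6g -> %.6g (self-loop mass dropped %.6g)\n",
              x$fiber_mass_before, x$fiber_mass_after,
              x$self_loop_mass_dropped))
  invisible(x)
}
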