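#' Default GraphML attribute-name mapping
#'
#' Attribute key names follow the CMTK convention for connectome GraphML
#' files (node label/hemisphere/position, edge fiber count, mean fiber
#' length, mean FA). Real-world files that use different key strings can be
#' read by overriding individual entries.
#'
#' @param ... named overrides, e.g. `fiber_count = "weight"`. Valid names:
#'   `label`, `hemisphere`, `x`, `y`, `z`, `fiber_count`, `mean_length`,
#'   `mean_fa`.
#' @return named character vector mapping internal field names to GraphML
#'   `attr.name` strings.
#' @examples
#' default_attribute_map(fiber_count = "number_of_fibers")
#' @export
default_attribute_map <- function(...) {
  map <- c(
    label = "dn_name",
    hemisphere = "dn_hemisphere",
    x = "dn_position_x",
    y = "dn_position_y",
    z = "dn_position_z",
    fiber_count = "number_of_fibers",
    mean_length = "fiber_length_mean",
    mean_fa = "FA_mean"
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(map))
    if (length(bad))
      stop_input("unknown attribute_map field(s): %s", paste(bad, collapse = ", "))
    map[names(ov)] <- ov
  }
  map
}

node_fields <- c("label", "hemisphere", "x", "y", "z")
edge_fields <- c("fiber_count", "mean_length", "mean_fa")

## graph-level keys used to round-trip container metadata
meta_keys <- c(resolution_label = "resolution_label", provenance = "provenance_json")

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a braingraph to GraphML
#'
#' Emits a GraphML file in the connectome dialect: an attribute-definition
#' section first, then nodes with coordinates and anatomical labels, then
#' undirected edges carrying the three weights (fiber count, mean streamline
#' length, mean FA). Floating-point weights are serialized with 17
#' significant digits so that [read_braingraph()] recovers them exactly;
#' averaged fiber counts are stored as-is, never rounded to integers.
#'
#' @param graph a `braingraph`.
#' @param path output file path.
#' @param attribute_map name mapping from [default_attribute_map()].
#' @return `path`, invisibly.
#' @export
write_braingraph <- function(graph, path, attribute_map = default_attribute_map()) {
  validate_braingraph(graph)
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  addkey <- function(id, domain, type) {
    xml2::xml_add_child(doc, "key", id = id, "for" = domain,
                        "attr.name" = id, "attr.type" = type)
  }
  addkey(attribute_map[["label"]], "node", "string")
  addkey(attribute_map[["hemisphere"]], "node", "string")
  for (f in c("x", "y", "z")) addkey(attribute_map[[f]], "node", "double")
  addkey(attribute_map[["fiber_count"]], "edge", "double")
  addkey(attribute_map[["mean_length"]], "edge", "double")
  addkey(attribute_map[["mean_fa"]], "edge", "double")
  for (mk in meta_keys) addkey(mk, "graph", "string")

  gnode <- xml2::xml_add_child(doc, "graph", id = "G",
                               edgedefault = "undirected")
  xml2::xml_add_child(
    xml2::xml_add_child(gnode, "data", key = meta_keys[["resolution_label"]]),
    xml2::xml_cdata(graph$resolution_label))
  prov <- as.character(jsonlite::toJSON(graph$provenance, auto_unbox = TRUE,
                                        digits = I(17), null = "null"))
  xml2::xml_add_child(
    xml2::xml_add_child(gnode, "data", key = meta_keys[["provenance"]]),
    xml2::xml_cdata(prov))

  n <- graph$nodes
  for (i in seq_len(nrow(n))) {
    nd <- xml2::xml_add_child(gnode, "node", id = as.character(n$id[i]))
    vals <- c(n$label[i], n$hemisphere[i], fmt17(n$x[i]), fmt17(n$y[i]),
              fmt17(n$z[i]))
    for (j in seq_along(node_fields)) {
      d <- xml2::xml_add_child(nd, "data", key = attribute_map[[node_fields[j]]])
      xml2::xml_text(d) <- vals[j]
    }
  }
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(gnode, "edge",
                              source = as.character(e$u[i]),
                              target = as.character(e$v[i]))
    vals <- c(fmt17(e$fiber_count[i]), fmt17(e$mean_length[i]),
              fmt17(e$mean_fa[i]))
    for (j in seq_along(edge_fields)) {
      d <- xml2::xml_add_child(ed, "data", key = attribute_map[[edge_fields[j]]])
      xml2::xml_text(d) <- vals[j]
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

## collect <data> children of one element into a named character vector,
## translating key ids to attr.name strings via keymap
data_values <- function(el, keymap) {
  ds <- xml2::xml_find_all(el, "./data")
  vals <- xml2::xml_text(ds)
  ids <- xml2::xml_attr(ds, "key")
  names(vals) <- ifelse(ids %in% names(keymap), keymap[ids], ids)
  vals
}

require_attr <- function(vals, key, what) {
  if (!key %in% names(vals))
    stop_input("missing GraphML attribute key '%s' on a %s element", key, what)
  vals[[key]]
}

#' Read a braingraph from GraphML
#'
#' Parses a GraphML file in the connectome dialect and returns a validated
#' [braingraph()]. Directed graphs are rejected rather than symmetrized;
#' self-loops, duplicate edges and out-of-range weights raise validation
#' errors; a missing attribute key raises a schema error naming the key.
#'
#' @param path path to a GraphML file.
#' @param attribute_map name mapping from [default_attribute_map()].
#' @return a `braingraph`.
#' @export
read_braingraph <- function(path, attribute_map = default_attribute_map()) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_input("malformed XML in %s: %s",
                                                 path, conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  keydefs <- xml2::xml_find_all(doc, "./key")
  keymap <- stats::setNames(xml2::xml_attr(keydefs, "attr.name"),
                            xml2::xml_attr(keydefs, "id"))
  keymap[is.na(keymap)] <- names(keymap)[is.na(keymap)]
  gnode <- xml2::xml_find_first(doc, "./graph")
  if (inherits(gnode, "xml_missing"))
    stop_input("no <graph> element in %s", path)
  if (identical(xml2::xml_attr(gnode, "edgedefault"), "directed"))
    stop_input("directed GraphML input is not supported; braingraphs are undirected")

  gvals <- data_values(gnode, keymap)
  resolution_label <- if (meta_keys[["resolution_label"]] %in% names(gvals))
    gvals[[meta_keys[["resolution_label"]]]] else "native"
  provenance <- if (meta_keys[["provenance"]] %in% names(gvals))
    jsonlite::fromJSON(gvals[[meta_keys[["provenance"]]]],
                       simplifyVector = TRUE) else list()
  if (!is.list(provenance)) provenance <- as.list(provenance)

  parse_id <- function(s, what) {
    id <- suppressWarnings(as.integer(s))
    if (any(is.na(id)))
      stop_input("non-integer %s id(s) in %s: %s", what, path,
                 paste(utils::head(s[is.na(id)], 3), collapse = ", "))
    id
  }

  nels <- xml2::xml_find_all(gnode, "./node")
  nodes <- if (length(nels)) {
    vals <- lapply(nels, data_values, keymap = keymap)
    data.frame(
      id = parse_id(xml2::xml_attr(nels, "id"), "node"),
      label = vapply(vals, require_attr, "", key = attribute_map[["label"]],
                     what = "node"),
      hemisphere = vapply(vals, require_attr, "",
                          key = attribute_map[["hemisphere"]], what = "node"),
      x = as.numeric(vapply(vals, require_attr, "",
                            key = attribute_map[["x"]], what = "node")),
      y = as.numeric(vapply(vals, require_attr, "",
                            key = attribute_map[["y"]], what = "node")),
      z = as.numeric(vapply(vals, require_attr, "",
                            key = attribute_map[["z"]], what = "node")),
      stringsAsFactors = FALSE
    )
  } else empty_nodes()

  eels <- xml2::xml_find_all(gnode, "./edge")
  edges <- if (length(eels)) {
    vals <- lapply(eels, data_values, keymap = keymap)
    data.frame(
      u = parse_id(xml2::xml_attr(eels, "source"), "edge source"),
      v = parse_id(xml2::xml_attr(eels, "target"), "edge target"),
      fiber_count = as.numeric(vapply(vals, require_attr, "",
                                      key = attribute_map[["fiber_count"]],
                                      what = "edge")),
      mean_length = as.numeric(vapply(vals, require_attr, "",
                                      key = attribute_map[["mean_length"]],
                                      what = "edge")),
      mean_fa = as.numeric(vapply(vals, require_attr, "",
                                  key = attribute_map[["mean_fa"]],
                                  what = "edge")),
      stringsAsFactors = FALSE
    )
  } else empty_edges()

  braingraph(nodes, edges, resolution_label = resolution_label,
             provenance = provenance)
}
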