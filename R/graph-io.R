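# Graph serialization: JSON, GraphML, openCypher script emission and replay.
#
# The JSON layout is nodes: id/labels/props, edges: id/src/dst/label/props
# plus the vocabulary registries and constraint list, so a deserialized graph
# enforces the same constraints as the original. GraphML has no list-valued
# attribute type, so list properties travel as a "json:"-prefixed string.
# Length-1 list properties round-trip as scalars in both formats.

#' Serialize a graph to JSON
#'
#' @param g A `property_graph`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
pg_to_json <- function(g, path = NULL) {
  nodes <- lapply(pg_node_ids(g), function(id) {
    n <- pg_node(g, id)
    list(id = id, labels = as.list(n$labels), props = box_props(n$props))
  })
  edges <- lapply(pg_edge_ids(g), function(id) {
    e <- pg_edge(g, id)
    list(id = e$id, src = e$source, dst = e$target, label = e$label,
         props = box_props(e$props))
  })
  doc <- list(
    format = "physiograph-graph", version = 1L,
    next_id = g$next_id,
    verlabs = as.list(g$verlabs), edgelabs = as.list(g$edgelabs),
    properties = as.list(g$props),
    constraints = lapply(g$constraints, function(con)
      list(kind = con$kind, target_label = con$target_label,
           property = con$property)),
    nodes = nodes, edges = edges
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

box_props <- function(props) {
  lapply(props, function(v) if (length(v) > 1) as.list(v) else v)
}

unbox_props <- function(props) {
  lapply(props, function(v) {
    if (is.list(v)) unlist(v) else v
  })
}

#' Deserialize a graph from JSON
#'
#' @param x A file path or JSON string produced by [pg_to_json()].
#' @return A `property_graph`.
#' @export
pg_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (!identical(doc$format, "physiograph-graph"))
    pg_abort("not a physiograph graph document", "pg_io_failure")
  g <- pg_new(seed_schema = FALSE)
  pg_register_label(g, unlist(doc$verlabs))
  pg_register_edge_label(g, unlist(doc$edgelabs))
  pg_register_property(g, unlist(doc$properties))
  id_map <- new.env(parent = emptyenv())
  for (n in doc$nodes) {
    new <- pg_create_node(g, unlist(n$labels), unbox_props(n$props))
    id_map[[as.character(n$id)]] <- new
  }
  for (e in doc$edges) {
    pg_create_edge(g, id_map[[as.character(e$src)]],
                   id_map[[as.character(e$dst)]], e$label,
                   unbox_props(e$props))
  }
  for (con in doc$constraints)
    pg_register_constraint(g, con$kind, con$target_label, con$property)
  rebuild_timeline_index(g)
  g
}

# after import, re-derive the shared timeline index from Timestamp nodes
rebuild_timeline_index <- function(g) {
  ids <- g$label_index[["Timestamp"]] %||% integer()
  if (length(ids) == 0) return(invisible(g))
  vals <- vapply(ids, function(id) as.numeric(pg_node(g, id)$props$value),
                 numeric(1))
  ord <- order(vals)
  g$ts_values <- vals[ord]
  g$ts_ids <- as.integer(ids[ord])
  g$timeline_experiments <- as.integer(g$label_index[["Experiment"]] %||%
                                         integer())
  invisible(g)
}

graphml_type <- function(v) {
  if (length(v) > 1) "string" else if (is.logical(v)) "boolean"
  else if (is.numeric(v)) "double" else "string"
}

graphml_encode <- function(v) {
  if (length(v) > 1)
    paste0("json:", jsonlite::toJSON(v, digits = NA))
  else if (is.logical(v)) tolower(as.character(v))
  else if (is.numeric(v)) format(v, digits = 15, scientific = FALSE)
  else as.character(v)
}

graphml_decode <- function(txt, type) {
  if (startsWith(txt, "json:"))
    return(unlist(jsonlite::fromJSON(substring(txt, 6))))
  switch(type,
         double = as.numeric(txt),
         boolean = as.logical(toupper(txt)),
         txt)
}

#' Export a graph to GraphML
#'
#' Node labels are joined with `:` into a `labels` attribute; edge labels go
#' into a `label` attribute; properties become typed GraphML keys
#' (list-valued properties are encoded as `json:`-prefixed strings).
#'
#' @param g A `property_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
pg_to_graphml <- function(g, path) {
  # collect property keys and their types per domain
  key_types <- list(node = list(), edge = list())
  for (id in pg_node_ids(g))
    for (nm in names(pg_node(g, id)$props))
      key_types$node[[nm]] <- graphml_type(pg_node(g, id)$props[[nm]])
  for (id in pg_edge_ids(g))
    for (nm in names(pg_edge(g, id)$props))
      key_types$edge[[nm]] <- graphml_type(pg_edge(g, id)$props[[nm]])

  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  add_key <- function(id, domain, name, type) {
    xml2::xml_add_child(doc, "key", id = id, "for" = domain,
                        attr.name = name, attr.type = type)
  }
  add_key("nlabels", "node", "labels", "string")
  add_key("elabel", "edge", "label", "string")
  for (nm in names(key_types$node))
    add_key(paste0("n_", nm), "node", nm, key_types$node[[nm]])
  for (nm in names(key_types$edge))
    add_key(paste0("e_", nm), "edge", nm, key_types$edge[[nm]])

  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  for (id in pg_node_ids(g)) {
    n <- pg_node(g, id)
    nd <- xml2::xml_add_child(graph, "node", id = paste0("n", id))
    d <- xml2::xml_add_child(nd, "data", key = "nlabels")
    xml2::xml_text(d) <- paste(n$labels, collapse = ":")
    for (nm in names(n$props)) {
      d <- xml2::xml_add_child(nd, "data", key = paste0("n_", nm))
      xml2::xml_text(d) <- graphml_encode(n$props[[nm]])
    }
  }
  for (id in pg_edge_ids(g)) {
    e <- pg_edge(g, id)
    ed <- xml2::xml_add_child(graph, "edge", id = paste0("e", id),
                              source = paste0("n", e$source),
                              target = paste0("n", e$target))
    d <- xml2::xml_add_child(ed, "data", key = "elabel")
    xml2::xml_text(d) <- e$label
    for (nm in names(e$props)) {
      d <- xml2::xml_add_child(ed, "data", key = paste0("e_", nm))
      xml2::xml_text(d) <- graphml_encode(e$props[[nm]])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a graph from GraphML
#'
#' Reads GraphML written by [pg_to_graphml()]. Labels and properties found in
#' the file are registered into the new graph's open registries; the default
#' schema constraints are re-registered afterwards.
#'
#' @param path GraphML file path.
#' @param seed_constraints Re-register the default integrity constraints
#'   (default `TRUE`).
#' @return A `property_graph`.
#' @export
pg_from_graphml <- function(path, seed_constraints = TRUE) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "gml")
  keys <- xml2::xml_find_all(doc, ".//gml:key", ns)
  key_info <- list()
  for (k in keys) {
    key_info[[xml2::xml_attr(k, "id")]] <-
      list(name = xml2::xml_attr(k, "attr.name"),
           type = xml2::xml_attr(k, "attr.type"))
  }
  g <- pg_new(seed_schema = FALSE)
  read_data <- function(el) {
    props <- list()
    labels <- NULL
    lab <- NULL
    for (d in xml2::xml_find_all(el, "./gml:data", ns)) {
      keyid <- xml2::xml_attr(d, "key")
      info <- key_info[[keyid]]
      txt <- xml2::xml_text(d)
      if (identical(keyid, "nlabels")) labels <- strsplit(txt, ":")[[1]]
      else if (identical(keyid, "elabel")) lab <- txt
      else props[[info$name]] <- graphml_decode(txt, info$type)
    }
    list(labels = labels, label = lab, props = props)
  }
  id_map <- new.env(parent = emptyenv())
  for (nd in xml2::xml_find_all(doc, ".//gml:node", ns)) {
    parsed <- read_data(nd)
    pg_register_label(g, parsed$labels)
    pg_register_property(g, names(parsed$props))
    new <- pg_create_node(g, parsed$labels, parsed$props)
    id_map[[xml2::xml_attr(nd, "id")]] <- new
  }
  for (ed in xml2::xml_find_all(doc, ".//gml:edge", ns)) {
    parsed <- read_data(ed)
    pg_register_edge_label(g, parsed$label)
    pg_register_property(g, names(parsed$props))
    pg_create_edge(g, id_map[[xml2::xml_attr(ed, "source")]],
                   id_map[[xml2::xml_attr(ed, "target")]],
                   parsed$label, parsed$props)
  }
  if (seed_constraints) {
    pg_register_constraint(g, "uniqueness", "Experiment", "name")
    pg_register_constraint(g, "uniqueness", "Participant", "user_id")
    pg_register_constraint(g, "uniqueness", "Timestamp", "value")
    pg_register_constraint(g, "uniqueness", "Measure", "signal_id")
    pg_register_constraint(g, "mandatory", "Channel", "type")
  }
  rebuild_timeline_index(g)
  g
}

cypher_value <- function(v) {
  one <- function(x) {
    if (is.character(x))
      paste0("'", gsub("'", "\\\\'", x), "'")
    else if (is.logical(x)) tolower(as.character(x))
    else format(x, digits = 15, scientific = FALSE)
  }
  if (length(v) > 1)
    paste0("[", paste(vapply(v, one, character(1)), collapse = ", "), "]")
  else one(v)
}

cypher_props <- function(props) {
  if (length(props) == 0) return("")
  body <- paste(vapply(names(props), function(nm)
    paste0(nm, ": ", cypher_value(props[[nm]])), character(1)),
    collapse = ", ")
  paste0(" {", body, "}")
}

#' Emit an openCypher script recreating the graph
#'
#' Produces constraint DDL (`CREATE CONSTRAINT ... ASSERT ... IS UNIQUE` /
#' `ASSERT EXISTS`) followed by one `CREATE` statement per node and per edge,
#' in id order, loadable into a Neo4j-compatible database. The text is
#' byte-stable for a given graph.
#'
#' @param g A `property_graph`.
#' @param path Optional output path.
#' @return Character vector of script lines (invisibly when `path` is given).
#' @export
pg_to_cypher <- function(g, path = NULL) {
  lines <- character()
  for (con in g$constraints) {
    lines <- c(lines, if (con$kind == "uniqueness")
      sprintf("CREATE CONSTRAINT ON (n:%s) ASSERT (n.%s) IS UNIQUE;",
              con$target_label, con$property)
    else
      sprintf("CREATE CONSTRAINT ON (n:%s) ASSERT EXISTS (n.%s);",
              con$target_label, con$property))
  }
  for (id in pg_node_ids(g)) {
    n <- pg_node(g, id)
    lines <- c(lines, sprintf("CREATE (v%d:%s%s);", id,
                              paste(n$labels, collapse = ":"),
                              cypher_props(n$props)))
  }
  for (id in pg_edge_ids(g)) {
    e <- pg_edge(g, id)
    lines <- c(lines, sprintf(
      "MATCH (a), (b) WHERE id(a) = %d AND id(b) = %d CREATE (a)-[:%s%s]->(b);",
      e$source, e$target, e$label, cypher_props(e$props)))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

parse_cypher_props <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(list())
  # split on commas outside quotes and brackets
  chars <- strsplit(txt, "")[[1]]
  depth <- 0; inq <- FALSE; parts <- character(); buf <- ""
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (inq) {
      if (ch == "\\" && i < length(chars)) { buf <- paste0(buf, chars[i + 1]); i <- i + 2; next }
      if (ch == "'") inq <- FALSE else buf <- paste0(buf, ch)
      if (ch == "'") buf <- paste0(buf, "\x01")  # marker: string value ended
      i <- i + 1; next
    }
    if (ch == "'") { inq <- TRUE; buf <- paste0(buf, "\x01") }
    else if (ch == "[") { depth <- depth + 1; buf <- paste0(buf, ch) }
    else if (ch == "]") { depth <- depth - 1; buf <- paste0(buf, ch) }
    else if (ch == "," && depth == 0) { parts <- c(parts, buf); buf <- "" }
    else buf <- paste0(buf, ch)
    i <- i + 1
  }
  parts <- c(parts, buf)
  props <- list()
  for (p in parts) {
    kv <- regmatches(p, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", p))[[1]]
    if (length(kv) < 3) next
    nm <- kv[2]; raw <- trimws(kv[3])
    props[[nm]] <- parse_cypher_value(raw)
  }
  props
}

parse_cypher_value <- function(raw) {
  if (startsWith(raw, "[")) {
    inner <- substr(raw, 2, nchar(raw) - 1)
    vals <- strsplit(inner, ",\\s*")[[1]]
    return(unlist(lapply(trimws(vals), parse_cypher_value)))
  }
  if (startsWith(raw, "\x01")) {
    return(gsub("\x01", "", raw))
  }
  if (raw %in% c("true", "false")) return(raw == "true")
  as.numeric(raw)
}

#' Replay an emitted openCypher script into a new graph
#'
#' Parses only the fixed dialect produced by [pg_to_cypher()] (there is no
#' general openCypher executor here) and rebuilds the graph through the
#' ordinary creation operations, so all integrity constraints are re-enforced
#' during replay.
#'
#' @param lines Character vector of script lines, or a file path.
#' @return A `property_graph`.
#' @export
pg_from_cypher <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  g <- pg_new(seed_schema = FALSE)
  pending_constraints <- list()
  id_map <- new.env(parent = emptyenv())
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec(
      "^CREATE CONSTRAINT ON \\(n:([A-Za-z_][A-Za-z0-9_]*)\\) ASSERT \\(n\\.([A-Za-z_][A-Za-z0-9_]*)\\) IS UNIQUE;$", ln))[[1]]
    if (length(m) == 3) {
      pending_constraints <- c(pending_constraints,
                               list(list("uniqueness", m[2], m[3])))
      next
    }
    m <- regmatches(ln, regexec(
      "^CREATE CONSTRAINT ON \\(n:([A-Za-z_][A-Za-z0-9_]*)\\) ASSERT EXISTS \\(n\\.([A-Za-z_][A-Za-z0-9_]*)\\);$", ln))[[1]]
    if (length(m) == 3) {
      pending_constraints <- c(pending_constraints,
                               list(list("mandatory", m[2], m[3])))
      next
    }
    m <- regmatches(ln, regexec(
      "^CREATE \\(v([0-9]+):([A-Za-z_:][A-Za-z0-9_:]*)( \\{(.*)\\})?\\);$", ln))[[1]]
    if (length(m) >= 3) {
      labels <- strsplit(m[3], ":")[[1]]
      props <- parse_cypher_props(if (length(m) >= 5) m[5] else "")
      pg_register_label(g, labels)
      pg_register_property(g, names(props))
      id_map[[m[2]]] <- pg_create_node(g, labels, props)
      next
    }
    m <- regmatches(ln, regexec(
      "^MATCH \\(a\\), \\(b\\) WHERE id\\(a\\) = ([0-9]+) AND id\\(b\\) = ([0-9]+) CREATE \\(a\\)-\\[:([A-Za-z_][A-Za-z0-9_]*)( \\{(.*)\\})?\\]->\\(b\\);$", ln))[[1]]
    if (length(m) >= 4) {
      props <- parse_cypher_props(if (length(m) >= 6) m[6] else "")
      pg_register_edge_label(g, m[4])
      pg_register_property(g, names(props))
      pg_create_edge(g, id_map[[m[2]]], id_map[[m[3]]], m[4], props)
      next
    }
    pg_abort(paste("unparseable script line:", ln), "pg_io_failure")
  }
  for (con in pending_constraints)
    pg_register_constraint(g, con[[1]], con[[2]], con[[3]])
  rebuild_timeline_index(g)
  g
}

# 9 significant digits: equality up to the last-ulp noise that textual
# serialization of doubles can introduce
props_signature <- function(props) {
  if (length(props) == 0) return("")
  nms <- sort(names(props))
  fmt <- function(v) {
    if (is.numeric(v)) sprintf("%.9g", v) else format(v)
  }
  paste(vapply(nms, function(nm)
    paste0(nm, "=", paste(fmt(props[[nm]]), collapse = ";")),
    character(1)), collapse = "|")
}

#' Test two graphs for isomorphism under creation-order id renaming
#'
#' Maps the i-th smallest node id of `a` to the i-th smallest node id of `b`
#' (serialization and replay preserve creation order) and then requires equal
#' labels and property maps per node and equal edge multisets (label,
#' properties, remapped endpoints).
#'
#' @param a,b Two `property_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
pg_isomorphic <- function(a, b) {
  na <- pg_node_ids(a); nb <- pg_node_ids(b)
  if (length(na) != length(nb)) return(FALSE)
  map <- stats::setNames(nb, as.character(na))
  for (i in seq_along(na)) {
    x <- pg_node(a, na[i]); y <- pg_node(b, nb[i])
    if (!setequal(x$labels, y$labels)) return(FALSE)
    if (!identical(props_signature(x$props), props_signature(y$props)))
      return(FALSE)
  }
  ea <- pg_edge_ids(a); eb <- pg_edge_ids(b)
  if (length(ea) != length(eb)) return(FALSE)
  sig <- function(g, ids, remap) {
    sort(vapply(ids, function(id) {
      e <- pg_edge(g, id)
      s <- if (remap) map[[as.character(e$source)]] else e$source
      t <- if (remap) map[[as.character(e$target)]] else e$target
      paste(s, t, e$label, props_signature(e$props), sep = "#")
    }, character(1)))
  }
  identical(sig(a, ea, TRUE), sig(b, eb, FALSE))
}
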