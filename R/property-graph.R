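# Labeled property graph store.
#
# A graph is the tuple (V, E, rho, lambda1, lambda2, sigma): a finite node set,
# a disjoint edge set, a total endpoint map giving each edge an ordered node
# pair, a total node-labelling map into non-empty label sets, a total
# edge-labelling map into single labels, and a partial property map over
# (V union E) x Prop. The store keeps all six components explicit, plus a
# registry of integrity constraints enforced transactionally on every
# mutation.

pg_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "pg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Default node-label vocabulary
#'
#' Node labels seeded into every new graph: experiment context
#' (`Experiment`, `Recording`, `Participant`, `Channel`), measure declarations
#' (`Measure` plus the kind labels `TimestampMeasure`, `EpochMeasure`,
#' `ElectrodeMeasure`), and the data layer (`SignalValue`, `Timestamp`).
#' The registry is open: [pg_register_label()] adds user-defined labels.
#'
#' @return Character vector of label names.
#' @export
default_node_labels <- function() {
  c("Experiment", "Recording", "Participant", "Channel",
    "Measure", "TimestampMeasure", "EpochMeasure", "ElectrodeMeasure",
    "SignalValue", "Timestamp")
}

#' Default edge-label vocabulary
#'
#' @return Character vector of edge label names.
#' @export
default_edge_labels <- function() {
  c("PART_OF", "TAKES_PART_IN", "TAKES", "HAS_RECORDING_TYPE",
    "HAS_MEASURE", "HAS_SIGNAL", "NEXT", "IN_SEC",
    "START_IN_SEC", "END_IN_SEC", "INFLUENCE_ON")
}

default_properties <- function() {
  c("name", "activity", "place", "user_id", "gender", "age",
    "type", "recording_standard",
    "signal_id", "datatype", "range", "fs", "value", "data",
    "delta", "theta", "alpha", "beta", "gamma",
    "GSR_min", "GSR_max", "GSR_avg", "no_of_peaks",
    "HRV_min", "HRV_max", "HRV_var", "HRV_mean",
    "IBI_min", "IBI_max", "IBI_var", "IBI_mean",
    "mi", "id", "source")
}

uniq_key <- function(label, property, value) {
  paste(label, property, paste(format(value, digits = 15), collapse = ","),
        sep = "\x1f")
}

#' Create an empty property graph
#'
#' @param seed_schema If `TRUE` (default) the label/property registries are
#'   seeded with the physiological-recording vocabulary
#'   ([default_node_labels()], [default_edge_labels()]) and the four default
#'   uniqueness constraints (`Experiment.name`, `Participant.user_id`,
#'   `Timestamp.value`, `Measure.signal_id`) plus the mandatory
#'   `Channel.type` constraint are registered.
#' @return A `property_graph` object (environment with reference semantics).
#' @export
pg_new <- function(seed_schema = TRUE) {
  g <- new.env(parent = emptyenv())
  g$nodes <- new.env(parent = emptyenv())
  g$edges <- new.env(parent = emptyenv())
  g$out <- new.env(parent = emptyenv())   # node id -> outgoing edge ids
  g$inc <- new.env(parent = emptyenv())   # node id -> incoming edge ids
  g$label_index <- new.env(parent = emptyenv())
  g$uniq <- new.env(parent = emptyenv())  # uniqueness index
  g$next_id <- 0L
  g$verlabs <- character()
  g$edgelabs <- character()
  g$props <- character()
  g$constraints <- list()
  # shared timeline index (see timeline.R)
  g$ts_values <- numeric()
  g$ts_ids <- integer()
  g$timeline_experiments <- integer()
  class(g) <- "property_graph"
  if (seed_schema) {
    pg_register_label(g, default_node_labels())
    pg_register_edge_label(g, default_edge_labels())
    pg_register_property(g, default_properties())
    pg_register_constraint(g, "uniqueness", "Experiment", "name")
    pg_register_constraint(g, "uniqueness", "Participant", "user_id")
    pg_register_constraint(g, "uniqueness", "Timestamp", "value")
    pg_register_constraint(g, "uniqueness", "Measure", "signal_id")
    pg_register_constraint(g, "mandatory", "Channel", "type")
  }
  g
}

#' Register vocabulary elements
#'
#' The node-label, edge-label and property-name sets are open registries;
#' creating an element with an unregistered label or property is an error,
#' so user-defined vocabulary must be registered first.
#'
#' @param g A `property_graph`.
#' @param label,property Character vector of names to add.
#' @return The graph, invisibly.
#' @export
pg_register_label <- function(g, label) {
  g$verlabs <- union(g$verlabs, label)
  invisible(g)
}

#' @rdname pg_register_label
#' @export
pg_register_edge_label <- function(g, label) {
  g$edgelabs <- union(g$edgelabs, label)
  invisible(g)
}

#' @rdname pg_register_label
#' @export
pg_register_property <- function(g, property) {
  g$props <- union(g$props, property)
  invisible(g)
}

validate_props <- function(g, props) {
  if (length(props) == 0) return(invisible(NULL))
  if (is.null(names(props)) || any(!nzchar(names(props))))
    pg_abort("all properties must be named", "pg_invalid_property")
  unknown <- setdiff(names(props), g$props)
  if (length(unknown))
    pg_abort(paste0("unregistered properties: ",
                    paste(unknown, collapse = ", "),
                    " (register with pg_register_property)"),
             "pg_unknown_property")
  bad <- vapply(props, function(v) {
    !(is.numeric(v) || is.character(v) || is.logical(v)) || length(v) < 1
  }, logical(1))
  if (any(bad))
    pg_abort("property values must be non-empty scalars or homogeneous vectors",
             "pg_invalid_property")
  invisible(NULL)
}

# drop NULL-valued entries: null is expressed by property absence
compact_props <- function(props) {
  props[!vapply(props, is.null, logical(1))]
}

check_node_constraints <- function(g, labels, props) {
  for (con in g$constraints) {
    if (!(con$target_label %in% labels)) next
    v <- props[[con$property]]
    if (con$kind == "mandatory") {
      if (is.null(v))
        pg_abort(sprintf("mandatory property '%s' missing for label '%s'",
                         con$property, con$target_label),
                 "pg_constraint_violation")
    } else if (con$kind == "uniqueness" && !is.null(v)) {
      key <- uniq_key(con$target_label, con$property, v)
      if (!is.null(g$uniq[[key]]))
        pg_abort(sprintf("uniqueness violated: %s.%s = %s already present",
                         con$target_label, con$property,
                         paste(v, collapse = ",")),
                 "pg_constraint_violation")
    }
  }
  invisible(NULL)
}

index_node_constraints <- function(g, id, labels, props, add = TRUE) {
  for (con in g$constraints) {
    if (con$kind != "uniqueness" || !(con$target_label %in% labels)) next
    v <- props[[con$property]]
    if (is.null(v)) next
    key <- uniq_key(con$target_label, con$property, v)
    if (add) g$uniq[[key]] <- id else rm(list = key, envir = g$uniq)
  }
  invisible(NULL)
}

#' Create a node
#'
#' Validates labels against the registry, checks every registered integrity
#' constraint and, only if all checks pass, inserts the node (transactional
#' reject semantics: a failing call leaves the graph untouched).
#'
#' @param g A `property_graph`.
#' @param labels Character vector (non-empty) of registered node labels.
#' @param props Named list of property values. Scalars (numeric, character,
#'   logical) or homogeneous vectors (list-valued properties such as `data`).
#'   `NULL` entries are dropped: null is expressed by property absence.
#' @return The integer id of the new node.
#' @export
pg_create_node <- function(g, labels, props = list()) {
  labels <- unique(as.character(labels))
  if (length(labels) == 0)
    pg_abort("a node needs at least one label", "pg_unknown_label")
  unknown <- setdiff(labels, g$verlabs)
  if (length(unknown))
    pg_abort(paste0("unregistered node labels: ",
                    paste(unknown, collapse = ", ")), "pg_unknown_label")
  props <- compact_props(props)
  validate_props(g, props)
  check_node_constraints(g, labels, props)
  id <- g$next_id + 1L
  g$next_id <- id
  key <- as.character(id)
  g$nodes[[key]] <- list(id = id, labels = labels, props = props)
  g$out[[key]] <- integer()
  g$inc[[key]] <- integer()
  for (lab in labels)
    g$label_index[[lab]] <- c(g$label_index[[lab]], id)
  index_node_constraints(g, id, labels, props, add = TRUE)
  id
}

#' Create a directed edge
#'
#' @param g A `property_graph`.
#' @param source,target Existing node ids; the edge is directed
#'   source -> target.
#' @param label A single registered edge label.
#' @param props Named list of edge properties.
#' @return The integer id of the new edge (ids are shared with nodes so the
#'   two identifier spaces stay disjoint).
#' @export
pg_create_edge <- function(g, source, target, label, props = list()) {
  skey <- as.character(source); tkey <- as.character(target)
  if (is.null(g$nodes[[skey]]) || is.null(g$nodes[[tkey]]))
    pg_abort("both edge endpoints must exist", "pg_missing_endpoint")
  if (length(label) != 1 || !(label %in% g$edgelabs))
    pg_abort(paste0("unregistered edge label: ", label), "pg_unknown_label")
  props <- compact_props(props)
  validate_props(g, props)
  id <- g$next_id + 1L
  g$next_id <- id
  g$edges[[as.character(id)]] <- list(id = id, source = source,
                                      target = target, label = label,
                                      props = props)
  g$out[[skey]] <- c(g$out[[skey]], id)
  g$inc[[tkey]] <- c(g$inc[[tkey]], id)
  id
}

# internal: used by the timeline layer when splicing NEXT chains
pg_delete_edge <- function(g, id) {
  key <- as.character(id)
  e <- g$edges[[key]]
  if (is.null(e)) pg_abort("no such edge", "pg_missing_endpoint")
  skey <- as.character(e$source); tkey <- as.character(e$target)
  g$out[[skey]] <- setdiff(g$out[[skey]], id)
  g$inc[[tkey]] <- setdiff(g$inc[[tkey]], id)
  rm(list = key, envir = g$edges)
  invisible(g)
}

#' Access a node or edge
#'
#' @param g A `property_graph`.
#' @param id Element id.
#' @return A list with fields `id`, `labels`, `props` (node) or `id`,
#'   `source`, `target`, `label`, `props` (edge).
#' @export
pg_node <- function(g, id) {
  n <- g$nodes[[as.character(id)]]
  if (is.null(n)) pg_abort(paste("no node with id", id), "pg_missing_endpoint")
  n
}

#' @rdname pg_node
#' @export
pg_edge <- function(g, id) {
  e <- g$edges[[as.character(id)]]
  if (is.null(e)) pg_abort(paste("no edge with id", id), "pg_missing_endpoint")
  e
}

#' @rdname pg_node
#' @export
pg_node_ids <- function(g) {
  sort(vapply(as.list(g$nodes), function(n) n$id, integer(1), USE.NAMES = FALSE))
}

#' @rdname pg_node
#' @export
pg_edge_ids <- function(g) {
  sort(vapply(as.list(g$edges), function(e) e$id, integer(1), USE.NAMES = FALSE))
}

# internal property setter with constraint maintenance
pg_set_property <- function(g, id, name, value, element = c("node", "edge")) {
  element <- match.arg(element)
  pg_register_property(g, name)
  key <- as.character(id)
  if (element == "node") {
    n <- g$nodes[[key]]
    if (is.null(n)) pg_abort("no such node", "pg_missing_endpoint")
    if (is.null(value)) return(invisible(g))
    newprops <- n$props
    newprops[[name]] <- value
    check <- setdiff(names(newprops), names(n$props))
    # uniqueness re-check for the touched property only
    for (con in g$constraints) {
      if (con$kind == "uniqueness" && con$target_label %in% n$labels &&
          con$property == name) {
        k <- uniq_key(con$target_label, name, value)
        holder <- g$uniq[[k]]
        if (!is.null(holder) && holder != id)
          pg_abort("uniqueness violated by property update",
                   "pg_constraint_violation")
        old <- n$props[[name]]
        if (!is.null(old))
          rm(list = uniq_key(con$target_label, name, old), envir = g$uniq)
        g$uniq[[k]] <- id
      }
    }
    n$props <- newprops
    g$nodes[[key]] <- n
  } else {
    e <- g$edges[[key]]
    if (is.null(e)) pg_abort("no such edge", "pg_missing_endpoint")
    if (is.null(value)) return(invisible(g))
    e$props[[name]] <- value
    g$edges[[key]] <- e
  }
  invisible(g)
}

#' Register an integrity constraint
#'
#' Uniqueness: no two nodes carrying `target_label` may share a value of
#' `property`. Mandatory: every node carrying `target_label` must have a
#' non-null `property`. Registration verifies the existing contents first and
#' fails (without registering) if they already violate the constraint.
#'
#' @param g A `property_graph`.
#' @param kind `"uniqueness"` or `"mandatory"`.
#' @param target_label Node label the constraint applies to.
#' @param property Property name.
#' @return The graph, invisibly.
#' @export
pg_register_constraint <- function(g, kind = c("uniqueness", "mandatory"),
                                   target_label, property) {
  kind <- match.arg(kind)
  con <- list(kind = kind, target_label = target_label, property = property)
  ids <- g$label_index[[target_label]]
  if (kind == "uniqueness") {
    seen <- new.env(parent = emptyenv())
    for (id in ids) {
      v <- g$nodes[[as.character(id)]]$props[[property]]
      if (is.null(v)) next
      k <- uniq_key(target_label, property, v)
      if (!is.null(seen[[k]]))
        pg_abort(sprintf("retroactive violation: duplicate %s.%s",
                         target_label, property), "pg_retroactive_violation")
      seen[[k]] <- id
    }
    for (k in ls(seen)) g$uniq[[k]] <- seen[[k]]
  } else {
    for (id in ids) {
      if (is.null(g$nodes[[as.character(id)]]$props[[property]]))
        pg_abort(sprintf("retroactive violation: %s node %d lacks %s",
                         target_label, id, property),
                 "pg_retroactive_violation")
    }
  }
  g$constraints <- c(g$constraints, list(con))
  invisible(g)
}

#' Batch constraint verification
#'
#' Re-checks every registered constraint from scratch, independently of the
#' incremental indexes maintained during mutation.
#'
#' @param g A `property_graph`.
#' @return Character vector of violation messages (empty when the graph is
#'   consistent).
#' @export
pg_verify_constraints <- function(g) {
  out <- character()
  for (con in g$constraints) {
    ids <- g$label_index[[con$target_label]]
    if (con$kind == "uniqueness") {
      vals <- vapply(ids, function(id) {
        v <- g$nodes[[as.character(id)]]$props[[con$property]]
        if (is.null(v)) NA_character_ else paste(format(v, digits = 15),
                                                 collapse = ",")
      }, character(1))
      vals <- vals[!is.na(vals)]
      if (anyDuplicated(vals))
        out <- c(out, sprintf("duplicate %s.%s", con$target_label,
                              con$property))
    } else {
      for (id in ids) {
        if (is.null(g$nodes[[as.character(id)]]$props[[con$property]]))
          out <- c(out, sprintf("%s node %d lacks %s", con$target_label, id,
                                con$property))
      }
    }
  }
  out
}

#' Match nodes or edges by label and property predicates
#'
#' Read-only pattern matching: label membership plus property predicates.
#' `props` entries are equality tests; `where` entries are
#' `list(property, op, value)` comparisons with
#' `op` in `<, <=, ==, >=, >, !=`.
#'
#' @param g A `property_graph`.
#' @param label Optional label to restrict to (node label or edge label
#'   depending on `what`).
#' @param props Named list of property = value equality predicates.
#' @param where Optional list of `list(property, op, value)` triples.
#' @param what `"nodes"` (default) or `"edges"`.
#' @return Sorted integer vector of matching element ids (empty on no match).
#' @export
pg_match <- function(g, label = NULL, props = list(), where = NULL,
                     what = c("nodes", "edges")) {
  what <- match.arg(what)
  test_props <- function(p) {
    for (nm in names(props)) {
      v <- p[[nm]]
      if (is.null(v) || length(v) != length(props[[nm]]) ||
          !isTRUE(all(v == props[[nm]]))) return(FALSE)
    }
    if (!is.null(where)) {
      for (w in where) {
        v <- p[[w[[1]]]]
        if (is.null(v)) return(FALSE)
        op <- switch(w[[2]], "<" = `<`, "<=" = `<=`, "==" = `==`, "=" = `==`,
                     ">=" = `>=`, ">" = `>`, "!=" = `!=`,
                     pg_abort("unknown operator", "pg_invalid_property"))
        if (!isTRUE(op(v, w[[3]]))) return(FALSE)
      }
    }
    TRUE
  }
  if (what == "nodes") {
    ids <- if (is.null(label)) pg_node_ids(g) else g$label_index[[label]]
    if (is.null(ids)) return(integer())
    keep <- vapply(ids, function(id)
      test_props(g$nodes[[as.character(id)]]$props), logical(1))
    sort(ids[keep])
  } else {
    ids <- pg_edge_ids(g)
    keep <- vapply(ids, function(id) {
      e <- g$edges[[as.character(id)]]
      (is.null(label) || e$label == label) && test_props(e$props)
    }, logical(1))
    sort(ids[keep])
  }
}

# adjacency helpers used throughout the query layer
out_edges <- function(g, id, label = NULL) {
  ids <- g$out[[as.character(id)]]
  if (is.null(ids) || is.null(label)) return(ids %||% integer())
  ids[vapply(ids, function(e) g$edges[[as.character(e)]]$label == label,
             logical(1))]
}

in_edges <- function(g, id, label = NULL) {
  ids <- g$inc[[as.character(id)]]
  if (is.null(ids) || is.null(label)) return(ids %||% integer())
  ids[vapply(ids, function(e) g$edges[[as.character(e)]]$label == label,
             logical(1))]
}

out_neighbors <- function(g, id, label = NULL) {
  vapply(out_edges(g, id, label), function(e) g$edges[[as.character(e)]]$target,
         integer(1))
}

in_neighbors <- function(g, id, label = NULL) {
  vapply(in_edges(g, id, label), function(e) g$edges[[as.character(e)]]$source,
         integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.property_graph <- function(x, ...) {
  cat(sprintf("<property_graph> %d nodes, %d edges, %d constraints\n",
              length(pg_node_ids(x)), length(pg_edge_ids(x)),
              length(x$constraints)))
  invisible(x)
}
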