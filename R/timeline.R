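# Experiment timeline: an ordered linked list of Timestamp nodes.
#
# A Timestamp node's value is the offset from the start of the recording in
# integer milliseconds; consecutive nodes are linked by NEXT edges and every
# signal in the graph binds to this shared chain (IN_SEC for timestamp
# signals, START_IN_SEC/END_IN_SEC for epoch signals). The uniqueness
# constraint on Timestamp.value makes the chain global to the graph: all
# experiments stored in one graph share the timeline, and each Experiment's
# TAKES edge points at the current head (earliest) node.

#' Create a timeline handle for an experiment
#'
#' @param g A `property_graph`.
#' @param experiment Experiment node id.
#' @return A `timeline` object (list of graph and experiment id).
#' @export
timeline_init <- function(g, experiment) {
  pg_node(g, experiment)  # must exist
  if (!(experiment %in% g$timeline_experiments))
    g$timeline_experiments <- c(g$timeline_experiments, as.integer(experiment))
  # if the chain already has a head, connect the experiment to it
  if (length(g$ts_ids) > 0 &&
      length(out_edges(g, experiment, "TAKES")) == 0)
    pg_create_edge(g, experiment, g$ts_ids[1], "TAKES")
  structure(list(g = g, experiment = as.integer(experiment)),
            class = "timeline")
}

#' Get or create a Timestamp node
#'
#' Returns the existing node when `value_ms` is already on the timeline;
#' otherwise creates a node and splices it into the NEXT chain so values
#' stay strictly increasing along the chain. When the new node becomes the
#' earliest, every experiment's TAKES edge is repointed to it.
#'
#' @param tl A `timeline` (or a `property_graph`, in which case no TAKES
#'   bookkeeping for a specific experiment is implied).
#' @param value_ms Non-negative integer milliseconds. Sub-millisecond values
#'   are rejected, not rounded.
#' @return The Timestamp node id.
#' @export
get_or_create_timestamp <- function(tl, value_ms) {
  g <- if (inherits(tl, "timeline")) tl$g else tl
  if (length(value_ms) != 1 || is.na(value_ms) || value_ms < 0)
    pg_abort("timestamp must be a single non-negative value",
             "pg_negative_value")
  if (abs(value_ms - round(value_ms)) > 1e-9)
    pg_abort("timestamps are integer milliseconds; sub-ms values are rejected",
             "pg_subms_value")
  value_ms <- round(value_ms)
  pos <- findInterval(value_ms, g$ts_values)
  if (pos >= 1 && g$ts_values[pos] == value_ms) return(g$ts_ids[pos])
  id <- pg_create_node(g, "Timestamp", list(value = value_ms))
  prev_id <- if (pos >= 1) g$ts_ids[pos] else NA_integer_
  next_id <- if (pos < length(g$ts_ids)) g$ts_ids[pos + 1] else NA_integer_
  if (!is.na(prev_id) && !is.na(next_id)) {
    # unlink prev -> next before splicing
    for (eid in out_edges(g, prev_id, "NEXT")) {
      if (pg_edge(g, eid)$target == next_id) pg_delete_edge(g, eid)
    }
  }
  if (!is.na(prev_id)) pg_create_edge(g, prev_id, id, "NEXT")
  if (!is.na(next_id)) pg_create_edge(g, id, next_id, "NEXT")
  g$ts_values <- append(g$ts_values, value_ms, after = pos)
  g$ts_ids <- append(g$ts_ids, id, after = pos)
  if (pos == 0) {
    # new head: repoint experiment TAKES edges
    for (ex in g$timeline_experiments) {
      for (eid in out_edges(g, ex, "TAKES")) pg_delete_edge(g, eid)
      pg_create_edge(g, ex, id, "TAKES")
    }
  }
  id
}

measure_kind <- function(g, measure) {
  labs <- pg_node(g, measure)$labels
  if ("TimestampMeasure" %in% labs) "timestamp"
  else if ("ElectrodeMeasure" %in% labs) "electrode"
  else if ("EpochMeasure" %in% labs) "epoch"
  else pg_abort("node is not a measure", "pg_kind_mismatch")
}

#' Attach a timestamp-signal series to a measure
#'
#' Creates one SignalValue node per sample, chained with NEXT edges, with the
#' measure's HAS_SIGNAL edge pointing at the first node and one IN_SEC edge
#' from the sample's Timestamp node. A missing sample (`NA`) becomes a node
#' without the `value` property.
#'
#' @param tl A `timeline`.
#' @param measure Measure node id with kind `timestamp`.
#' @param t_ms Non-decreasing integer millisecond offsets.
#' @param values Numeric values, same length as `t_ms` (may contain `NA`).
#' @return Id of the first SignalValue node, or `NA` for an empty series.
#' @export
attach_timestamp_values <- function(tl, measure, t_ms, values) {
  g <- tl$g
  if (measure_kind(g, measure) != "timestamp")
    pg_abort("measure is not a timestamp measure", "pg_kind_mismatch")
  if (length(t_ms) != length(values))
    pg_abort("t_ms and values must have equal length", "pg_unsorted_input")
  if (length(t_ms) == 0) return(NA_integer_)
  if (is.unsorted(t_ms))
    pg_abort("timestamp series must be non-decreasing in time",
             "pg_unsorted_input")
  prev <- NA_integer_
  first <- NA_integer_
  for (i in seq_along(t_ms)) {
    props <- if (is.na(values[i])) list() else list(value = values[i])
    sv <- pg_create_node(g, "SignalValue", props)
    ts <- get_or_create_timestamp(tl, t_ms[i])
    pg_create_edge(g, ts, sv, "IN_SEC")
    if (is.na(prev)) {
      pg_create_edge(g, measure, sv, "HAS_SIGNAL")
      first <- sv
    } else {
      pg_create_edge(g, prev, sv, "NEXT")
    }
    prev <- sv
  }
  first
}

#' Attach an epoch-signal series to a measure
#'
#' Creates one SignalValue node per epoch with START_IN_SEC and END_IN_SEC
#' edges from the boundary Timestamp nodes (shared with every other signal on
#' the timeline via get-or-create). A scalar payload is stored as the settled
#' `value` property; a vector payload is stored as the raw `data` array.
#'
#' @param tl A `timeline`.
#' @param measure Measure node id with kind `epoch` or `electrode`.
#' @param start_ms,end_ms Integer millisecond epoch boundaries,
#'   `start_ms[i] < end_ms[i]`, starts strictly increasing.
#' @param payloads List of scalar values or numeric vectors (one per epoch);
#'   `NA` scalars yield nodes without a value.
#' @param allow_overlap Permit overlapping epochs (sliding windows); fixed
#'   epoching requires `end_ms[i] <= start_ms[i+1]`.
#' @return Id of the first SignalValue node, or `NA` for an empty series.
#' @export
attach_epoch_values <- function(tl, measure, start_ms, end_ms, payloads,
                                allow_overlap = FALSE) {
  g <- tl$g
  if (!(measure_kind(g, measure) %in% c("epoch", "electrode")))
    pg_abort("measure is not an epoch or electrode measure",
             "pg_kind_mismatch")
  n <- length(start_ms)
  if (length(end_ms) != n || length(payloads) != n)
    pg_abort("start_ms, end_ms and payloads must have equal length",
             "pg_overlapping_epochs")
  if (n == 0) return(NA_integer_)
  if (any(end_ms <= start_ms))
    pg_abort("each epoch must satisfy start < end", "pg_overlapping_epochs")
  if (n > 1 && any(diff(start_ms) <= 0))
    pg_abort("epoch starts must be strictly increasing",
             "pg_overlapping_epochs")
  if (!allow_overlap && n > 1 && any(start_ms[-1] < end_ms[-n]))
    pg_abort("epochs overlap", "pg_overlapping_epochs")
  prev <- NA_integer_
  first <- NA_integer_
  for (i in seq_len(n)) {
    p <- payloads[[i]]
    props <- if (length(p) > 1) list(data = as.numeric(p))
    else if (length(p) == 1 && !is.na(p)) list(value = p)
    else list()
    sv <- pg_create_node(g, "SignalValue", props)
    ts0 <- get_or_create_timestamp(tl, start_ms[i])
    ts1 <- get_or_create_timestamp(tl, end_ms[i])
    pg_create_edge(g, ts0, sv, "START_IN_SEC")
    pg_create_edge(g, ts1, sv, "END_IN_SEC")
    if (is.na(prev)) {
      pg_create_edge(g, measure, sv, "HAS_SIGNAL")
      first <- sv
    } else {
      pg_create_edge(g, prev, sv, "NEXT")
    }
    prev <- sv
  }
  first
}

#' Walk the timeline chain
#'
#' @param g A `property_graph`.
#' @return Data frame of Timestamp node ids and values in chain order
#'   (following NEXT from the head).
#' @export
timeline_chain <- function(g) {
  if (length(g$ts_ids) == 0)
    return(data.frame(id = integer(), value = numeric()))
  id <- g$ts_ids[1]
  ids <- integer(); vals <- numeric()
  while (!is.na(id)) {
    ids <- c(ids, id)
    vals <- c(vals, as.numeric(pg_node(g, id)$props$value))
    nxt <- out_neighbors(g, id, "NEXT")
    nxt <- nxt[nxt %in% g$ts_ids]
    id <- if (length(nxt) == 1) nxt else NA_integer_
  }
  data.frame(id = ids, value = vals)
}

# ordered SignalValue chain for a measure, with epoch boundaries
measure_chain <- function(g, measure) {
  roots <- out_neighbors(g, measure, "HAS_SIGNAL")
  if (length(roots) == 0)
    return(data.frame(id = integer(), start_ms = numeric(),
                      end_ms = numeric()))
  id <- roots[1]
  ids <- integer(); starts <- numeric(); ends <- numeric()
  while (!is.na(id)) {
    ids <- c(ids, id)
    s_in <- in_neighbors(g, id, "IN_SEC")
    s_st <- in_neighbors(g, id, "START_IN_SEC")
    s_en <- in_neighbors(g, id, "END_IN_SEC")
    if (length(s_in) == 1) {
      starts <- c(starts, as.numeric(pg_node(g, s_in)$props$value))
      ends <- c(ends, NA_real_)
    } else {
      starts <- c(starts,
                  if (length(s_st)) as.numeric(pg_node(g, s_st[1])$props$value)
                  else NA_real_)
      ends <- c(ends,
                if (length(s_en)) as.numeric(pg_node(g, s_en[1])$props$value)
                else NA_real_)
    }
    nxt <- out_neighbors(g, id, "NEXT")
    id <- if (length(nxt) == 1) nxt else NA_integer_
  }
  data.frame(id = ids, start_ms = starts, end_ms = ends)
}
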