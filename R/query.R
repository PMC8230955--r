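# Retrieval layer: the five canonical competency questions, tabular export,
# and per-epoch feature-vector assembly, executed natively against the
# in-memory graph, plus emission of the equivalent openCypher text.

#' CQ1: experiments holding a given measure on a given channel type
#'
#' Experiments that have a recording whose channel of type `channel_type`
#' carries a measure named `measure_name`.
#'
#' @param g A `property_graph`.
#' @param channel_type Channel type string.
#' @param measure_name Measure name.
#' @return Sorted integer vector of Experiment node ids.
#' @export
find_experiments <- function(g, channel_type, measure_name) {
  hits <- integer()
  for (e in g$label_index[["Experiment"]] %||% integer()) {
    recs <- in_neighbors(g, e, "PART_OF")
    for (r in recs) {
      for (ch in out_neighbors(g, r, "HAS_RECORDING_TYPE")) {
        if (!identical(pg_node(g, ch)$props$type, channel_type)) next
        for (m in out_neighbors(g, ch, "HAS_MEASURE")) {
          if (identical(pg_node(g, m)$props$name, measure_name)) {
            hits <- c(hits, e)
          }
        }
      }
    }
  }
  sort(unique(hits))
}

#' CQ2: measures of a given name on channels of a given type
#'
#' @inheritParams find_experiments
#' @return Sorted integer vector of Measure node ids.
#' @export
find_signals <- function(g, channel_type, measure_name) {
  hits <- integer()
  for (ch in g$label_index[["Channel"]] %||% integer()) {
    if (!identical(pg_node(g, ch)$props$type, channel_type)) next
    for (m in out_neighbors(g, ch, "HAS_MEASURE")) {
      if (identical(pg_node(g, m)$props$name, measure_name))
        hits <- c(hits, m)
    }
  }
  sort(unique(hits))
}

measure_by_signal_id <- function(g, signal_id) {
  ids <- pg_match(g, label = "Measure", props = list(signal_id = signal_id))
  if (length(ids) == 0)
    pg_abort(paste("no measure with signal_id", signal_id),
             "pg_unknown_signal")
  ids[1]
}

#' CQ3: time series of one signal
#'
#' Rows follow the SignalValue chain. Timestamp signals carry the sample
#' time in `start_ms` with `end_ms` all `NA`; epoch and electrode signals
#' carry both boundaries. Settled scalar values fill the `value` column;
#' raw arrays (calculated-value signals) are returned in the `data` list
#' column when no settled value exists.
#'
#' @param g A `property_graph`.
#' @param signal_id Integer signal id.
#' @return A `signal_table` data frame with columns `start_ms`, `end_ms`,
#'   `value`, `data`.
#' @export
get_time_series <- function(g, signal_id) {
  m <- measure_by_signal_id(g, signal_id)
  chain <- measure_chain(g, m)
  vals <- rep(NA_real_, nrow(chain))
  dats <- rep(list(NULL), nrow(chain))
  for (i in seq_len(nrow(chain))) {
    p <- pg_node(g, chain$id[i])$props
    if (!is.null(p$value)) vals[i] <- p$value
    if (!is.null(p$data)) dats[i] <- list(p$data)
  }
  structure(data.frame(start_ms = chain$start_ms, end_ms = chain$end_ms,
                       value = vals, data = I(dats)),
            class = c("signal_table", "data.frame"))
}

#' Declare a restriction for CQ5
#'
#' @param signal_id Signal whose value is tested at each shared start
#'   timestamp.
#' @param op Comparison operator: one of `<, <=, =, ==, >=, >, !=`.
#' @param constant Right-hand constant.
#' @param property Node property tested (default `"value"`).
#' @return A `restriction` list.
#' @export
restriction <- function(signal_id, op, constant, property = "value") {
  if (!op %in% c("<", "<=", "=", "==", ">=", ">", "!="))
    pg_abort("unknown restriction operator", "pg_invalid_params")
  structure(list(signal_id = signal_id, op = op, constant = constant,
                 property = property), class = "restriction")
}

signal_value_map <- function(g, signal_id, property = "value") {
  m <- measure_by_signal_id(g, signal_id)
  chain <- measure_chain(g, m)
  vals <- vapply(chain$id, function(id) {
    v <- pg_node(g, id)$props[[property]]
    if (is.null(v) || length(v) != 1) NA_real_ else as.numeric(v)
  }, numeric(1))
  list(start_ms = chain$start_ms, value = vals)
}

#' CQ4/CQ5: multivariate time series over shared start timestamps
#'
#' The first signal anchors the rows; each further signal contributes a
#' column joined on the shared start Timestamp node (left join: a signal
#' with no value at an anchor timestamp yields `NA`, mirroring OPTIONAL
#' MATCH). Restrictions (CQ5) keep only rows where every restricted
#' signal's value at that start timestamp satisfies its predicate; a missing
#' value fails every predicate.
#'
#' @param g A `property_graph`.
#' @param signal_ids Integer vector; the first id is the anchor.
#' @param restrictions Optional list of [restriction()] objects.
#' @return A `signal_table` data frame: `start_ms`, `end_ms`, then one
#'   column `s<signal_id>` per signal.
#' @export
get_multivariate <- function(g, signal_ids, restrictions = NULL) {
  anchor <- get_time_series(g, signal_ids[1])
  out <- data.frame(start_ms = anchor$start_ms, end_ms = anchor$end_ms)
  out[[paste0("s", signal_ids[1])]] <- anchor$value
  if (length(signal_ids) > 1) {
    for (sid in signal_ids[-1]) {
      mp <- signal_value_map(g, sid)
      idx <- match(out$start_ms, mp$start_ms)
      out[[paste0("s", sid)]] <- ifelse(is.na(idx), NA_real_,
                                        mp$value[idx])
    }
  }
  if (!is.null(restrictions)) {
    keep <- rep(TRUE, nrow(out))
    for (r in restrictions) {
      mp <- signal_value_map(g, r$signal_id, r$property)
      idx <- match(out$start_ms, mp$start_ms)
      v <- ifelse(is.na(idx), NA_real_, mp$value[idx])
      op <- switch(r$op, "<" = `<`, "<=" = `<=`, "=" = `==`, "==" = `==`,
                   ">=" = `>=`, ">" = `>`, "!=" = `!=`)
      ok <- op(v, r$constant)
      ok[is.na(ok)] <- FALSE  # null fails every predicate
      keep <- keep & ok
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("signal_table", "data.frame"))
}

#' Tabular export of a channel type's signal values
#'
#' One row per SignalValue of every electrode measure under channels of the
#' given type, with `n` requested value properties plus the seven metadata
#' columns `experiment`, `source_database`, `participant`, `channel_type`,
#' `measure_name`, `epoch_start`, `epoch_end` (n + 7 columns in total).
#'
#' @param g A `property_graph`.
#' @param channel_type Channel type string.
#' @param value_props Character vector of the n SignalValue properties to
#'   export.
#' @return A data frame with `length(value_props) + 7` columns.
#' @export
export_signal_table <- function(g, channel_type, value_props) {
  rows <- list()
  for (ch in g$label_index[["Channel"]] %||% integer()) {
    if (!identical(pg_node(g, ch)$props$type, channel_type)) next
    recs <- in_neighbors(g, ch, "HAS_RECORDING_TYPE")
    for (r in recs) {
      exps <- out_neighbors(g, r, "PART_OF")
      parts <- in_neighbors(g, r, "TAKES_PART_IN")
      exp_id <- if (length(exps)) {
        p <- pg_node(g, exps[1])$props
        p$id %||% p$name %||% exps[1]
      } else NA
      part_id <- if (length(parts)) {
        p <- pg_node(g, parts[1])$props
        p$id %||% p$user_id %||% parts[1]
      } else NA
      src <- pg_node(g, r)$props$source %||% NA
      for (m in channel_measures(g, ch, kind = "electrode")) {
        mname <- pg_node(g, m)$props$name
        chain <- measure_chain(g, m)
        for (i in seq_len(nrow(chain))) {
          p <- pg_node(g, chain$id[i])$props
          row <- list(experiment = exp_id, source_database = src,
                      participant = part_id, channel_type = channel_type,
                      measure_name = mname)
          for (vp in value_props) {
            v <- p[[vp]]
            row[[vp]] <- if (is.null(v) || length(v) != 1) NA else v
          }
          row$epoch_start <- chain$start_ms[i]
          row$epoch_end <- chain$end_ms[i]
          rows[[length(rows) + 1]] <- row
        }
      }
    }
  }
  if (length(rows) == 0) {
    cols <- c("experiment", "source_database", "participant", "channel_type",
              "measure_name", value_props, "epoch_start", "epoch_end")
    df <- as.data.frame(stats::setNames(rep(list(logical()), length(cols)),
                                        cols))
    return(df)
  }
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Per-epoch feature vectors for a recording
#'
#' Concatenates, per epoch and in deterministic order: the five band powers
#' for each EEG electrode (configured order), the eight HRV/IBI statistics
#' for each ECG electrode, the four skin-conductance peak values, then the
#' pairwise `mi` edge values for EEG electrode pairs in lexicographic order.
#' For the standard montage (14 EEG electrodes, left/right ECG, one GSR)
#' this yields 5*14 + 8*2 + 4 = 90 node-level values plus 14*13/2 = 91
#' edge-level values: 181 features.
#'
#' @param g A `property_graph`.
#' @param handle A `recording_handle` whose calculators have been applied.
#' @param eeg_order Optional character vector fixing the EEG electrode
#'   order; default is the lexicographic electrode-name order.
#' @param annotation_labels If `TRUE` (default), valence/arousal annotation
#'   measures found on an `Annotation` channel contribute label columns,
#'   including the affect-quadrant class (HVHA/HVLA/LVHA/LVLA from the signs
#'   of valence and arousal).
#' @return List with `features` (epochs x p numeric matrix with column
#'   names), `epochs` (start/end ms), and `labels` (data frame or `NULL`).
#' @export
extract_feature_vectors <- function(g, handle, eeg_order = NULL,
                                    annotation_labels = TRUE) {
  ch_of_type <- function(type) {
    hit <- handle$channels[vapply(handle$channels, function(ch)
      identical(pg_node(g, ch)$props$type, type), logical(1))]
    if (length(hit)) hit[1] else NA_integer_
  }
  eeg_ch <- ch_of_type("EEG"); ecg_ch <- ch_of_type("ECG")
  gsr_ch <- ch_of_type("GSR"); ann_ch <- ch_of_type("Annotation")

  m_name <- function(m) as.character(pg_node(g, m)$props$name)
  ordered_measures <- function(ch, order_names = NULL) {
    if (is.na(ch)) return(integer())
    ms <- channel_measures(g, ch, kind = "electrode")
    nms <- vapply(ms, m_name, character(1))
    if (!is.null(order_names)) {
      missing <- setdiff(order_names, nms)
      if (length(missing))
        pg_abort(paste("electrodes not present:",
                       paste(missing, collapse = ", ")),
                 "pg_unknown_signal")
      ms[match(order_names, nms)]
    } else ms[order(nms)]
  }
  eeg_ms <- ordered_measures(eeg_ch, eeg_order)
  ecg_ms <- ordered_measures(ecg_ch)
  gsr_ms <- ordered_measures(gsr_ch)

  band_props <- default_bands()$name
  ecg_props <- c("HRV_min", "HRV_max", "HRV_var", "HRV_mean",
                 "IBI_min", "IBI_max", "IBI_var", "IBI_mean")
  gsr_props <- c("GSR_min", "GSR_max", "GSR_avg", "no_of_peaks")

  all_ms <- c(eeg_ms, ecg_ms, gsr_ms)
  if (length(all_ms) == 0)
    pg_abort("recording has no electrode measures", "pg_unknown_signal")
  chains <- lapply(all_ms, function(m) measure_chain(g, m))
  nep <- unique(vapply(chains, nrow, integer(1)))
  if (length(nep) != 1)
    pg_abort("channels are not epoched on the same grid", "pg_grid_mismatch")
  ref <- chains[[1]][c("start_ms", "end_ms")]
  for (i in seq_along(chains)) {
    if (!isTRUE(all.equal(ref, chains[[i]][c("start_ms", "end_ms")],
                          check.attributes = FALSE)))
      pg_abort("channels are not epoched on the same grid",
               "pg_grid_mismatch")
  }
  names(chains) <- vapply(all_ms, m_name, character(1))

  cols <- character(); getters <- list()
  add <- function(colname, fun) {
    cols[[length(cols) + 1]] <<- colname
    getters[[length(getters) + 1]] <<- fun
  }
  node_getter <- function(chain, prop) {
    force(chain); force(prop)
    function(ei) {
      v <- pg_node(g, chain$id[ei])$props[[prop]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }
  }
  for (m in eeg_ms) {
    nm <- m_name(m)
    for (bp in band_props) add(paste(nm, bp, sep = "."),
                               node_getter(chains[[nm]], bp))
  }
  for (m in ecg_ms) {
    nm <- m_name(m)
    for (p in ecg_props) add(paste(nm, p, sep = "."),
                             node_getter(chains[[nm]], p))
  }
  for (m in gsr_ms) {
    nm <- m_name(m)
    for (p in gsr_props) add(paste(nm, p, sep = "."),
                             node_getter(chains[[nm]], p))
  }
  # pairwise EEG mi edges, lexicographic electrode order
  if (length(eeg_ms) > 1) {
    eeg_names <- vapply(eeg_ms, m_name, character(1))
    lex <- sort(eeg_names)
    for (a in seq_len(length(lex) - 1)) {
      for (b in (a + 1):length(lex)) {
        ca <- chains[[lex[a]]]; cb <- chains[[lex[b]]]
        local({
          ca <- ca; cb <- cb
          add(paste0("mi.", lex[a], "_", lex[b]), function(ei) {
            for (eid in out_edges(g, ca$id[ei], "INFLUENCE_ON")) {
              e <- pg_edge(g, eid)
              if (e$target == cb$id[ei])
                return(as.numeric(e$props$mi %||% NA_real_))
            }
            NA_real_
          })
        })
      }
    }
  }
  feat <- matrix(NA_real_, nrow = nep, ncol = length(cols),
                 dimnames = list(NULL, unlist(cols)))
  for (ei in seq_len(nep)) {
    for (ci in seq_along(getters)) feat[ei, ci] <- getters[[ci]](ei)
  }

  labels <- NULL
  if (annotation_labels && !is.na(ann_ch)) {
    ann_ms <- channel_measures(g, ann_ch)
    nms <- vapply(ann_ms, m_name, character(1))
    lab_df <- data.frame(row.names = seq_len(nep))
    for (i in seq_along(ann_ms)) {
      chain <- measure_chain(g, ann_ms[i])
      if (nrow(chain) != nep) next
      vals <- vapply(chain$id, function(id) {
        v <- pg_node(g, id)$props$value
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1))
      lab_df[[nms[i]]] <- vals
    }
    if (all(c("valence", "arousal") %in% names(lab_df))) {
      lab_df$quadrant <- ifelse(
        lab_df$valence > 0,
        ifelse(lab_df$arousal > 0, "HVHA", "HVLA"),
        ifelse(lab_df$arousal > 0, "LVHA", "LVLA"))
    }
    if (ncol(lab_df) > 0) labels <- lab_df
  }
  list(features = feat, epochs = ref, labels = labels)
}

quote_cy <- function(x) paste0("'", gsub("'", "\\\\'", x), "'")

#' Emit the generic retrieval queries as openCypher text
#'
#' Instantiates the fixed query patterns for the five competency questions
#' with concrete parameters; the text is byte-stable for golden tests.
#'
#' @param cq Integer 1-5.
#' @param channel_type,measure_name Parameters for CQ1/CQ2.
#' @param signal_ids Signal ids for CQ3-CQ5 (first is the anchor).
#' @param restrictions List of [restriction()] objects (CQ5).
#' @return Character vector of query lines.
#' @export
emit_cypher_query <- function(cq, channel_type = NULL, measure_name = NULL,
                              signal_ids = NULL, restrictions = NULL) {
  if (cq == 1) {
    return(c(sprintf(
      "MATCH (e:Experiment)<-[:PART_OF]-()-[:HAS_RECORDING_TYPE]->(c:Channel {type:%s})-[:HAS_MEASURE]->(m {name:%s})",
      quote_cy(channel_type), quote_cy(measure_name)),
      "RETURN e"))
  }
  if (cq == 2) {
    return(c(sprintf(
      "MATCH (c:Channel {type:%s})-[:HAS_MEASURE]->(m {name:%s})",
      quote_cy(channel_type), quote_cy(measure_name)),
      "RETURN m"))
  }
  anchor <- signal_ids[1]
  lines <- sprintf(
    "MATCH (m1 {signal_id:%s})-[:HAS_SIGNAL]->(s1_root:SignalValue)-[:NEXT*0..]->(s1:SignalValue)<-[:IN_SEC]-(startTimestamp:Timestamp)",
    anchor)
  if (cq == 5 && length(restrictions)) {
    for (i in seq_along(restrictions)) {
      lines <- c(lines, sprintf(
        ", (r%d {signal_id:%s})-[:HAS_SIGNAL]->(rs%d_root:SignalValue)-[:NEXT*0..]->(rs%d:SignalValue)<-[:IN_SEC]-(startTimestamp)",
        i, restrictions[[i]]$signal_id, i, i))
    }
    preds <- vapply(seq_along(restrictions), function(i)
      sprintf("rs%d.%s %s %s", i, restrictions[[i]]$property,
              restrictions[[i]]$op, restrictions[[i]]$constant),
      character(1))
    lines <- c(lines, paste("WHERE", paste(preds, collapse = " AND ")))
  }
  lines <- c(lines,
             "OPTIONAL MATCH (s1:SignalValue)<-[:END_IN_SEC]-(endTimestamp:Timestamp)")
  rest <- if (length(signal_ids) > 1) signal_ids[-1] else integer()
  for (i in seq_along(rest)) {
    lines <- c(lines, sprintf(
      "OPTIONAL MATCH (m%d {signal_id:%s})-[:HAS_SIGNAL]->(s%d_root:SignalValue)-[:NEXT*0..]->(s%d:SignalValue)<-[:IN_SEC]-(startTimestamp)",
      i + 1, rest[i], i + 1, i + 1))
  }
  ret <- paste0("RETURN startTimestamp.value, endTimestamp.value, ",
                paste(sprintf("s%d.value", seq_len(length(rest) + 1)),
                      collapse = ", "))
  c(lines, ret)
}
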