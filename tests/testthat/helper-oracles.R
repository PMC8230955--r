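# Shared fixtures and independent oracles for the suite.

# edge table scanned straight out of the store (used by query oracles)
edge_table <- function(g) {
  ids <- pg_edge_ids(g)
  do.call(rbind, c(list(data.frame(src = integer(), dst = integer(),
                                   label = character())),
                   lapply(ids, function(id) {
                     e <- pg_edge(g, id)
                     data.frame(src = e$source, dst = e$target,
                                label = e$label)
                   })))
}

node_prop <- function(g, id, prop) {
  v <- pg_node(g, id)$props[[prop]]
  if (is.null(v)) NA else v
}

# brute-force CQ1 oracle: relational joins over the full edge table
oracle_find_experiments <- function(g, channel_type, measure_name) {
  et <- edge_table(g)
  part_of <- et[et$label == "PART_OF", ]
  hrt <- et[et$label == "HAS_RECORDING_TYPE", ]
  hm <- et[et$label == "HAS_MEASURE", ]
  hits <- integer()
  for (i in seq_len(nrow(part_of))) {
    rec <- part_of$src[i]; ex <- part_of$dst[i]
    chans <- hrt$dst[hrt$src == rec]
    chans <- chans[vapply(chans, function(ch)
      identical(node_prop(g, ch, "type"), channel_type), logical(1))]
    for (ch in chans) {
      ms <- hm$dst[hm$src == ch]
      if (any(vapply(ms, function(m)
        identical(node_prop(g, m, "name"), measure_name), logical(1))))
        hits <- c(hits, ex)
    }
  }
  sort(unique(hits))
}

oracle_find_signals <- function(g, channel_type, measure_name) {
  et <- edge_table(g)
  hm <- et[et$label == "HAS_MEASURE", ]
  hits <- integer()
  for (i in seq_len(nrow(hm))) {
    ch <- hm$src[i]; m <- hm$dst[i]
    if (identical(node_prop(g, ch, "type"), channel_type) &&
        identical(node_prop(g, m, "name"), measure_name))
      hits <- c(hits, m)
  }
  sort(unique(hits))
}

# randomized small session graph; returns the graph plus construction-time
# ground truth for every signal (the query oracle)
rand_session_graph <- function(seed) {
  set.seed(seed)
  g <- pg_new()
  truth <- list(signals = list())
  sid <- 0
  types <- c("EEG", "ECG", "GSR", "Annotation")
  for (xi in seq_len(sample(1:2, 1))) {
    e <- create_experiment(g, sprintf("exp%d", xi))
    p <- create_participant(g, 100 + xi)
    n_ch <- sample(1:3, 1)
    chspecs <- lapply(sample(types, n_ch, replace = TRUE), channel_spec)
    h <- create_recording(g, e, p, chspecs)
    tl <- timeline_init(g, e)
    for (ci in seq_along(h$channels)) {
      ch_type <- pg_node(g, h$channels[ci])$props$type
      n_m <- sample(1:3, 1)
      for (mi in seq_len(n_m)) {
        sid <- sid + 1
        mname <- sample(c("F4", "AF3", "left", "right", "GSR",
                          "valence", "arousal", "temp"), 1)
        kind <- sample(c("timestamp", "epoch"), 1)
        spec <- if (kind == "epoch")
          measure_spec(sid, "epoch", mname, datatype = "float",
                       range = "0..1 inclusive")
        else measure_spec(sid, "timestamp", mname, datatype = "float",
                          range = "0..1 inclusive")
        m <- attach_measures(g, h$channels[ci], list(spec))
        nep <- sample(2:4, 1)
        if (kind == "epoch") {
          starts <- (seq_len(nep) - 1) * 1000
          vals <- round(runif(nep), 3)
          # occasional missing value
          vals[runif(nep) < 0.15] <- NA
          attach_epoch_values(tl, m, starts, starts + 1000, as.list(vals))
          truth$signals[[as.character(sid)]] <- list(
            experiment = e, channel_type = ch_type, name = mname,
            kind = kind, start_ms = starts, end_ms = starts + 1000,
            value = vals)
        } else {
          t_ms <- (seq_len(nep) - 1) * 1000
          vals <- round(runif(nep), 3)
          vals[runif(nep) < 0.15] <- NA
          attach_timestamp_values(tl, m, t_ms, vals)
          truth$signals[[as.character(sid)]] <- list(
            experiment = e, channel_type = ch_type, name = mname,
            kind = kind, start_ms = t_ms, end_ms = rep(NA_real_, nep),
            value = vals)
        }
      }
    }
  }
  list(g = g, truth = truth)
}

# small electrode-channel graph built from raw signals; used for sizing and
# calculator conservation checks
build_electrode_graph <- function(f, t, m, te = NULL, window = NULL) {
  g <- pg_new()
  e <- create_experiment(g, "sz")
  p <- create_participant(g, 1)
  h <- create_recording(g, e, p, list(channel_spec("EEG")))
  lists <- lapply(seq_len(m), function(i)
    list(spec = measure_spec(i, "electrode", sprintf("E%02d", i)),
         series = raw_signal(stats::rnorm(round(f * t)), f)))
  import_signals(g, h, h$channels[1], lists, epoch_s = te, window = window,
                 preprocess_cfg = FALSE)
  apply_calculators(g, calculator_job(
    h$channels[1], channel_measures(g, h$channels[1], "electrode"),
    rel_calcs = list(mi = function(x, y, fs) mutual_information(x, y)$mi)))
  g
}

channel_measures <- physiograph:::channel_measures

# the default synthetic session is expensive; build it once per test run
.session_cache <- new.env()
default_session <- function(seed = 42) {
  key <- as.character(seed)
  if (is.null(.session_cache[[key]])) {
    dir <- tempfile(sprintf("sess%s_", key))
    res <- gen_session(session_recipe(seed = seed), dir = dir)
    sess <- ingest_session(res$dir)
    for (ch in sess$handle$channels)
      apply_channel_calculators(sess$g, ch)
    .session_cache[[key]] <- list(res = res, sess = sess)
  }
  .session_cache[[key]]
}
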