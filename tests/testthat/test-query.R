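# Retrieval: competency questions, tabular export, feature vectors, cypher.

test_that("experiment and signal search match targeted examples", {
  g <- pg_new()
  e <- create_experiment(g, "exp1")
  h <- create_recording(g, e, create_participant(g, 1),
                        list(channel_spec("EEG"), channel_spec("GSR")))
  attach_measures(g, h$channels[1], list(measure_spec(1, "electrode", "F4")))
  attach_measures(g, h$channels[2], list(measure_spec(2, "electrode", "GSR")))
  expect_identical(find_experiments(g, "EEG", "F4"), e)
  expect_length(find_experiments(g, "ECG", "F4"), 0)
  expect_identical(find_experiments(g, "GSR", "GSR"), e)
  expect_length(find_signals(g, "EEG", "F4"), 1)
  expect_length(find_signals(g, "EEG", "AF3"), 0)
  expect_length(find_experiments(pg_new(), "EEG", "F4"), 0)
})

test_that("native queries equal brute-force oracles on random graphs", {
  types <- c("EEG", "ECG", "GSR", "Annotation")
  names_pool <- c("F4", "AF3", "left", "right", "GSR", "valence",
                  "arousal", "temp")
  for (seed in 1:25) {
    built <- rand_session_graph(seed)
    g <- built$g
    for (ty in types) for (nm in names_pool) {
      expect_identical(find_experiments(g, ty, nm),
                       oracle_find_experiments(g, ty, nm))
      expect_identical(find_signals(g, ty, nm),
                       oracle_find_signals(g, ty, nm))
    }
    # CQ3 against construction-time ground truth
    for (sid in names(built$truth$signals)) {
      tr <- built$truth$signals[[sid]]
      ts <- get_time_series(g, as.numeric(sid))
      expect_equal(ts$start_ms, tr$start_ms)
      expect_equal(ts$end_ms, tr$end_ms)
      expect_equal(ts$value, as.numeric(tr$value))
    }
  }
})

test_that("time series of timestamp signals carry null epoch ends", {
  built <- rand_session_graph(31)
  tr <- built$truth$signals
  ts_ids <- names(tr)[vapply(tr, function(x) x$kind == "timestamp",
                             logical(1))]
  for (sid in ts_ids) {
    ts <- get_time_series(built$g, as.numeric(sid))
    expect_true(all(is.na(ts$end_ms)))
  }
  expect_error(get_time_series(built$g, 10^6), class = "pg_unknown_signal")
})

test_that("multivariate retrieval left-joins on shared start timestamps", {
  g <- pg_new()
  e <- create_experiment(g, "e")
  tl <- timeline_init(g, e)
  h <- create_recording(g, e, create_participant(g, 1),
                        list(channel_spec("Annotation")))
  ms <- attach_measures(g, h$channels[1], list(
    measure_spec(1, "epoch", "valence", datatype = "float", range = "1..9"),
    measure_spec(2, "epoch", "arousal", datatype = "float", range = "1..9")))
  starts <- c(0, 20000, 40000)
  attach_epoch_values(tl, ms[1], starts, starts + 20000, list(5, 6, 2))
  # arousal missing at the last epoch start
  attach_epoch_values(tl, ms[2], starts[1:2], starts[1:2] + 20000,
                      list(1, 9))
  mv <- get_multivariate(g, c(1, 2))
  expect_identical(nrow(mv), 3L)
  expect_equal(mv$s1, c(5, 6, 2))
  expect_equal(mv$s2, c(1, 9, NA))
  # single signal, no restrictions, equals its own time series
  ts <- get_time_series(g, 1)
  one <- get_multivariate(g, 1)
  expect_equal(one$start_ms, ts$start_ms)
  expect_equal(one$s1, ts$value)
  # restriction oracle: filter the unrestricted table
  r <- list(restriction(1, ">=", 5))
  restricted <- get_multivariate(g, c(1, 2), restrictions = r)
  expect_equal(restricted, mv[mv$s1 >= 5, ], ignore_attr = TRUE)
  # a restriction on a missing value drops the row
  r2 <- list(restriction(2, "<", 100))
  expect_identical(nrow(get_multivariate(g, c(1, 2), restrictions = r2)), 2L)
})

test_that("export tables have n + 7 columns with the metadata layout", {
  built <- default_session()
  tab <- export_signal_table(built$sess$g, "EEG", c("alpha", "beta"))
  expect_identical(ncol(tab), 2L + 7L)
  expect_identical(names(tab)[1:5],
                   c("experiment", "source_database", "participant",
                     "channel_type", "measure_name"))
  expect_identical(names(tab)[8:9], c("epoch_start", "epoch_end"))
  expect_identical(nrow(tab), 14L * 6L)
  expect_true(all(is.finite(tab$alpha)))
})

test_that("feature vectors assemble in the documented order and length", {
  built <- default_session()
  fv <- extract_feature_vectors(built$sess$g, built$sess$handle)
  expect_identical(ncol(fv$features), 181L)
  expect_identical(nrow(fv$features), 6L)
  node_cols <- !startsWith(colnames(fv$features), "mi.")
  expect_identical(sum(node_cols), 90L)
  expect_identical(sum(!node_cols), 91L)
  expect_false(anyNA(fv$features))
  # order: EEG band powers, then ECG stats, then GSR, then mi pairs
  expect_identical(colnames(fv$features)[1:5],
                   paste("AF3", c("delta", "theta", "alpha", "beta", "gamma"),
                         sep = "."))
  expect_identical(colnames(fv$features)[71], "left.HRV_min")
  expect_identical(colnames(fv$features)[87], "GSR.GSR_min")
  expect_identical(colnames(fv$features)[91], "mi.AF3_AF4")
  # labels carry the affect quadrant from the valence/arousal signs
  expect_identical(names(fv$labels), c("valence", "arousal", "quadrant"))
  expect_true(all(fv$labels$quadrant %in% c("HVHA", "HVLA", "LVHA", "LVLA")))
  v <- built$res$truth$annotations$valence
  a <- built$res$truth$annotations$arousal
  expect_equal(fv$labels$valence, v)
  expect_identical(fv$labels$quadrant[1],
                   if (v[1] > 0) { if (a[1] > 0) "HVHA" else "HVLA"
                   } else { if (a[1] > 0) "LVHA" else "LVLA" })
  # a custom electrode order is respected
  fv2 <- extract_feature_vectors(built$sess$g, built$sess$handle,
                                 eeg_order = rev(sort(electrodes_1020_14())))
  expect_identical(colnames(fv2$features)[1], "T8.delta")
  # reduced montage follows the closed form 5 m + m(m-1)/2
  g <- pg_new()
  e <- create_experiment(g, "small")
  h <- create_recording(g, e, create_participant(g, 5),
                        list(channel_spec("EEG")))
  set.seed(19)
  lists <- lapply(1:2, function(i)
    list(spec = measure_spec(i, "electrode", c("F3", "F4")[i]),
         series = raw_signal(rnorm(128 * 40), 128)))
  import_signals(g, h, h$channels[1], lists, epoch_s = 20,
                 preprocess_cfg = FALSE)
  apply_channel_calculators(g, h$channels[1])
  fv3 <- extract_feature_vectors(g, h)
  expect_identical(ncol(fv3$features), 11L)
})

test_that("emitted cypher instantiates the generic query patterns", {
  q2 <- emit_cypher_query(2, channel_type = "EEG", measure_name = "F4")
  expect_true(any(grepl("(c:Channel {type:'EEG'})-[:HAS_MEASURE]->",
                        q2, fixed = TRUE)))
  q1 <- emit_cypher_query(1, channel_type = "GSR", measure_name = "GSR")
  expect_true(any(grepl("MATCH (e:Experiment)<-[:PART_OF]-()",
                        q1, fixed = TRUE)))
  q5 <- emit_cypher_query(5, signal_ids = c(1, 2),
                          restrictions = list(restriction(3, ">=", 5)))
  expect_true(any(grepl("WHERE rs1.value >= 5", q5, fixed = TRUE)))
  expect_true(any(grepl("OPTIONAL MATCH", q5)))
  # byte-stability
  expect_identical(q5, emit_cypher_query(5, signal_ids = c(1, 2),
                                         restrictions = list(
                                           restriction(3, ">=", 5))))
})
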