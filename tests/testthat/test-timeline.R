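# Timeline: ordered Timestamp chain and signal binding.

test_that("timestamps splice into a strictly increasing NEXT chain", {
  g <- pg_new()
  e <- create_experiment(g, "e")
  tl <- timeline_init(g, e)
  head1 <- get_or_create_timestamp(tl, 0)
  expect_identical(pg_node(g, head1)$props$value, 0)
  vals <- c(40000, 20000)   # out-of-order insertion
  for (v in vals) get_or_create_timestamp(tl, v)
  chain <- timeline_chain(g)
  expect_identical(chain$value, sort(c(0, vals)))  # sort oracle
  # |NEXT among timestamps| = n - 1
  nxt <- pg_match(g, label = "NEXT", what = "edges")
  ts_ids <- chain$id
  n_ts_next <- sum(vapply(nxt, function(eid) {
    ed <- pg_edge(g, eid)
    ed$source %in% ts_ids && ed$target %in% ts_ids
  }, logical(1)))
  expect_identical(n_ts_next, nrow(chain) - 1L)
  expect_error(get_or_create_timestamp(tl, -5), class = "pg_negative_value")
  expect_error(get_or_create_timestamp(tl, 10.5), class = "pg_subms_value")
  # idempotent
  expect_identical(get_or_create_timestamp(tl, 20000),
                   chain$id[chain$value == 20000])
})

test_that("interleaved insertion of sorted grids equals batch insertion", {
  build <- function(order) {
    g <- pg_new()
    tl <- timeline_init(g, create_experiment(g, "e"))
    for (v in order) get_or_create_timestamp(tl, v)
    timeline_chain(g)$value
  }
  set.seed(9)
  grids <- list(seq(0, 10000, by = 1000), seq(500, 9500, by = 1500),
                seq(0, 9000, by = 3000))
  interleaved <- unlist(grids)[order(rep(seq_along(grids),
                                         lengths(grids)))]  # round-robin-ish
  batch <- sort(unique(unlist(grids)))
  expect_identical(build(interleaved), batch)
  expect_identical(build(sample(unlist(grids))), batch)
})

test_that("the TAKES edge follows the head timestamp", {
  g <- pg_new()
  e <- create_experiment(g, "e")
  tl <- timeline_init(g, e)
  get_or_create_timestamp(tl, 5000)
  takes <- function() {
    eids <- pg_match(g, label = "TAKES", what = "edges")
    pg_node(g, pg_edge(g, eids)$target)$props$value
  }
  expect_identical(takes(), 5000)
  get_or_create_timestamp(tl, 1000)  # new earliest
  expect_identical(takes(), 1000)
  expect_length(pg_match(g, label = "TAKES", what = "edges"), 1)
})

test_that("timestamp series create the documented node/edge counts", {
  g <- pg_new()
  e <- create_experiment(g, "e")
  tl <- timeline_init(g, e)
  h <- create_recording(g, e, create_participant(g, 1),
                        list(channel_spec("Annotation")))
  m <- attach_measures(g, h$channels[1],
                       list(measure_spec(1, "timestamp", "temp",
                                         datatype = "float",
                                         range = "30..45 inclusive")))
  # 1 Hz, 3 samples, middle one missing
  first <- attach_timestamp_values(tl, m, c(0, 1000, 2000), c(36.5, NA, 36.7))
  svs <- pg_match(g, label = "SignalValue")
  expect_length(svs, 3)
  expect_length(pg_match(g, label = "IN_SEC", what = "edges"), 3)
  # 2 NEXT edges between signal values
  nxt <- pg_match(g, label = "NEXT", what = "edges")
  sv_next <- sum(vapply(nxt, function(eid) {
    ed <- pg_edge(g, eid)
    ed$source %in% svs && ed$target %in% svs
  }, logical(1)))
  expect_identical(sv_next, 2L)
  # HAS_SIGNAL points at the chain root; the missing sample has no value
  expect_identical(physiograph:::out_neighbors(g, m, "HAS_SIGNAL"), first)
  middle <- physiograph:::out_neighbors(g, first, "NEXT")
  expect_null(pg_node(g, middle)$props$value)
  # empty series leaves the measure unbound
  m2 <- attach_measures(g, h$channels[1],
                        list(measure_spec(2, "timestamp", "t2",
                                          datatype = "float", range = "0..1")))
  expect_true(is.na(attach_timestamp_values(tl, m2, numeric(), numeric())))
  expect_length(physiograph:::out_edges(g, m2, "HAS_SIGNAL"), 0)
  expect_error(attach_timestamp_values(tl, m2, c(100, 0), c(1, 2)),
               class = "pg_unsorted_input")
})

test_that("epoch series bind via START/END_IN_SEC and share timestamps", {
  g <- pg_new()
  e <- create_experiment(g, "e")
  tl <- timeline_init(g, e)
  h <- create_recording(g, e, create_participant(g, 1),
                        list(channel_spec("ECG")))
  ms <- attach_measures(g, h$channels[1], list(
    measure_spec(1, "epoch", "valence", datatype = "float",
                 range = "1..9 inclusive"),
    measure_spec(2, "epoch", "arousal", datatype = "float",
                 range = "1..9 inclusive")))
  # 20 s epochs starting at 0 ms
  starts <- c(0, 20000, 40000); ends <- starts + 20000
  first <- attach_epoch_values(tl, ms[1], starts, ends, list(5.1, 6.2, 3.3))
  attach_epoch_values(tl, ms[2], starts, ends, list(1.0, 2.0, 3.0))
  # epoch 1: START_IN_SEC from value 0, END_IN_SEC from value 20000
  st <- physiograph:::in_neighbors(g, first, "START_IN_SEC")
  en <- physiograph:::in_neighbors(g, first, "END_IN_SEC")
  expect_identical(pg_node(g, st)$props$value, 0)
  expect_identical(pg_node(g, en)$props$value, 20000)
  # identical grids create timestamps once: 4 boundary values in total
  expect_length(pg_match(g, label = "Timestamp"), 4)
  # start < end for every epoch signal value
  chain <- physiograph:::measure_chain(g, ms[1])
  expect_true(all(chain$start_ms < chain$end_ms))
  expect_error(
    attach_epoch_values(tl, ms[1], c(0, 10000), c(20000, 30000),
                        list(1, 2)),
    class = "pg_overlapping_epochs")
  expect_error(attach_timestamp_values(tl, ms[1], 0, 1),
               class = "pg_kind_mismatch")
})
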