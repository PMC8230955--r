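# Epoching, preprocessing and bulk import.

test_that("fixed epoching yields floor(t / te) full epochs", {
  # 1 Hz, 60 s, 20 s epochs -> 3 epochs of 20 samples / 20000 ms span
  ep <- epochize(raw_signal(rnorm(60), 1), epoch_s = 20)
  expect_identical(nrow(ep), 3L)
  expect_true(all(lengths(ep$samples) == 20))
  expect_identical(ep$end_ms - ep$start_ms, rep(20000, 3))
  # shorter than one epoch -> empty
  expect_identical(nrow(epochize(raw_signal(rnorm(10), 1), epoch_s = 20)), 0L)
  # randomized conservation against the closed form
  set.seed(4)
  for (i in 1:20) {
    f <- sample(c(1, 2, 4, 8, 16), 1)
    t <- sample(5:60, 1)
    te <- sample(1:10, 1)
    ep <- epochize(raw_signal(rnorm(f * t), f), epoch_s = te)
    expect_identical(nrow(ep), as.integer(floor(t / te)))
  }
})

test_that("sliding windows yield floor((ft - w) / (w - o)) windows", {
  # 10 Hz, 10 s, w = 20, o = 10 -> floor((100 - 20) / 10) = 8 windows
  ep <- epochize(raw_signal(rnorm(100), 10), window = list(w = 20, o = 10))
  expect_identical(nrow(ep), 8L)
  expect_true(all(lengths(ep$samples) == 20))
  expect_true(all(diff(ep$start_ms) == 1000))
  expect_error(epochize(raw_signal(rnorm(100), 10),
                        window = list(w = 10, o = 10)),
               class = "pg_invalid_params")
  set.seed(5)
  for (i in 1:20) {
    f <- sample(c(2, 4, 8, 16), 1)
    t <- sample(5:30, 1)
    w <- sample(8:32, 1)
    o <- sample(0:(w - 1), 1)
    ep <- epochize(raw_signal(rnorm(f * t), f), window = list(w = w, o = o))
    expect_identical(nrow(ep),
                     as.integer(max(0, floor((f * t - w) / (w - o)))))
  }
})

test_that("band-pass filtering attenuates out-of-band tones as designed", {
  fs <- 256
  tt <- (0:(10 * fs - 1)) / fs
  tone <- raw_signal(sin(2 * pi * 50 * tt), fs)
  filtered <- preprocess(tone, bpf_low_hz = 0.5, bpf_high_hz = 45)
  rms <- function(x) sqrt(mean(x^2))
  measured <- rms(filtered$samples) / rms(tone$samples)
  expect_lt(measured, 0.10)
  # oracle: analytic frequency response of the chosen FIR applied twice
  ntaps <- min(513, 2 * floor(length(tone$samples) / 8) + 1)
  h <- signal::fir1(ntaps - 1, c(0.5, 45) / (fs / 2), type = "pass")
  hf <- abs(sum(as.numeric(h) * exp(-1i * 2 * pi * 50 / fs *
                                      seq_along(h))))^2  # forward+backward
  expect_lt(abs(measured - hf), 0.05)
  # duration preserved within one sample
  expect_identical(length(filtered$samples), length(tone$samples))
  # all-null config is the identity
  ident <- preprocess(tone)
  expect_identical(ident$samples, tone$samples)
  expect_error(preprocess(tone, bpf_high_hz = 200),
               class = "pg_nyquist_violation")
})

test_that("resampling preserves duration within one output sample", {
  fs <- 256
  x <- raw_signal(rnorm(10 * fs), fs)
  y <- preprocess(x, resample_hz = 128)
  expect_lte(abs(length(y$samples) - 1280), 1)
  expect_identical(y$fs, 128)
})

test_that("import binds electrode signals and enforces a shared grid", {
  g <- pg_new()
  e <- create_experiment(g, "exp1")
  h <- create_recording(g, e, create_participant(g, 1),
                        list(channel_spec("EEG"), channel_spec("ECG")))
  # 14 electrodes, 128 Hz, 120 s, 20 s epochs -> 6 epochs x 14 measures
  set.seed(6)
  lists <- lapply(seq_len(14), function(i)
    list(spec = measure_spec(i, "electrode", electrodes_1020_14()[i]),
         series = raw_signal(rnorm(128 * 120), 128)))
  ms <- import_signals(g, h, h$channels[1], lists, epoch_s = 20,
                       preprocess_cfg = FALSE)
  expect_length(ms, 14)
  expect_length(pg_match(g, label = "SignalValue"), 84)
  # mismatched grids (different durations) are rejected before mutation
  n_before <- length(pg_node_ids(g))
  bad <- list(
    list(spec = measure_spec(20, "electrode", "left"),
         series = raw_signal(rnorm(256 * 120), 256)),
    list(spec = measure_spec(21, "electrode", "right"),
         series = raw_signal(rnorm(256 * 60), 256)))
  expect_error(import_signals(g, h, h$channels[2], bad, epoch_s = 20,
                              preprocess_cfg = FALSE),
               class = "pg_grid_mismatch")
  expect_identical(length(pg_node_ids(g)), n_before)
  # re-import with an already-used signal_id is rejected, not duplicated
  expect_error(import_signals(g, h, h$channels[1], lists[1], epoch_s = 20,
                              preprocess_cfg = FALSE),
               class = "pg_constraint_violation")
  expect_length(pg_match(g, label = "SignalValue"), 84)
})

test_that("signal CSV dialects round-trip", {
  d <- tempfile(); dir.create(d)
  ts <- data.frame(t_ms = c(0, 1000, 2000), value = c(1.5, 2.5, 3.5))
  write_signal_csv(ts, file.path(d, "ts.csv"), "timestamp")
  expect_equal(read_signal_csv(file.path(d, "ts.csv"), "timestamp"), ts)
  ep <- data.frame(start_ms = c(0, 1000), end_ms = c(1000, 2000),
                   value = c(4.25, 5))
  write_signal_csv(ep, file.path(d, "ep.csv"), "epoch")
  expect_equal(read_signal_csv(file.path(d, "ep.csv"), "epoch"), ep)
  # epoch payload arrays via the v1;v2;... column
  epl <- data.frame(start_ms = 0, end_ms = 1000)
  epl$value <- I(list(c(1, 2, 3)))
  write_signal_csv(epl, file.path(d, "epl.csv"), "epoch")
  back <- read_signal_csv(file.path(d, "epl.csv"), "epoch")
  expect_equal(back$value[[1]], c(1, 2, 3))
  raw <- raw_signal(c(0.1, 0.2, 0.3), 10)
  write_signal_csv(raw, file.path(d, "raw.csv"), "raw")
  expect_equal(read_signal_csv(file.path(d, "raw.csv"), "raw", fs = 10)$samples,
               raw$samples)
})
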