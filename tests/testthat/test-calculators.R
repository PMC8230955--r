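# Feature calculators: band power, ECG, GSR, mutual information, and the
# calculator application over a channel's signal network.

test_that("a pure 10 Hz tone concentrates its power in the alpha band", {
  fs <- 128
  x <- sin(2 * pi * 10 * (0:(20 * fs - 1)) / fs)
  bp <- eeg_bandpower(x, fs)
  total <- sum(unlist(bp))
  expect_gte(bp$alpha, 0.9 * total)
  # independent periodogram oracle on the same samples
  per <- Mod(stats::fft(x))^2 / length(x)
  freqs <- (seq_along(x) - 1) * fs / length(x)
  half <- freqs <= fs / 2
  alpha_per <- sum(per[half & freqs >= 8 & freqs < 12])
  total_per <- sum(per[half & freqs >= 0.5 & freqs < 100])
  expect_gte(alpha_per, 0.9 * total_per)
  expect_equal(bp$alpha / total, alpha_per / total_per, tolerance = 0.02)
})

test_that("zero input yields zero power in all bands", {
  bp <- eeg_bandpower(rep(0, 2560), 128)
  expect_identical(unlist(bp), c(delta = 0, theta = 0, alpha = 0,
                                 beta = 0, gamma = 0))
})

test_that("white-noise band powers scale with bandwidth", {
  set.seed(11)
  fs <- 256
  bp <- unlist(eeg_bandpower(rnorm(20 * fs), fs))
  widths <- c(delta = 3.5, theta = 4, alpha = 4, beta = 18, gamma = 70)
  ratio <- (bp / sum(bp)) / (widths / sum(widths))
  expect_true(all(abs(ratio - 1) < 0.25))
})

test_that("multitaper and periodogram totals agree on broadband noise", {
  set.seed(12)
  fs <- 256
  x <- rnorm(20 * fs)
  n <- length(x)
  bp_total <- sum(unlist(eeg_bandpower(x, fs)))
  per <- Mod(stats::fft(x))^2 / n^2  # per-bin contribution to mean power
  freqs <- (0:(n - 1)) * fs / n
  band <- (freqs >= 0.5 & freqs < 100) |
    (freqs > fs - 100 & freqs <= fs - 0.5)
  expect_lt(abs(bp_total / sum(per[band]) - 1), 0.15)
})

test_that("slepian tapers are orthonormal with near-unit concentrations", {
  d <- dpss_tapers(256, 4, 7)
  expect_lt(max(abs(crossprod(d$tapers) - diag(7))), 1e-10)
  expect_true(all(d$eigen > 0.9 & d$eigen <= 1))
  expect_true(all(diff(d$eigen) <= 1e-6))  # decreasing concentration
  # interpolated long tapers stay close to orthonormal
  d2 <- dpss_tapers(2560, 4, 7)
  expect_lt(max(abs(crossprod(d2$tapers) - diag(7))), 0.05)
  expect_true(all(d2$eigen > 0.9))
})

test_that("GSR peak detection recovers injected SCR counts", {
  fs <- 32
  # flat signal: no deflection, no peaks
  flat <- gsr_features(rep(1, 20 * fs), fs)
  expect_identical(flat$no_of_peaks, 0L)
  expect_true(is.na(flat$GSR_max))
  # three injected bumps above the amplitude threshold
  set.seed(13)
  recipe <- session_recipe(seed = 13, duration_s = 60, epoch_s = 60,
                           gsr = list(peak_times_s = c(10, 25, 40)))
  gsr <- gen_gsr(recipe)
  feats <- gsr_features(gsr$signal$samples, fs)
  expect_identical(feats$no_of_peaks, 3L)
  # a single clean bump: min = max = avg = its amplitude
  kern <- physiograph:::scr_kernel(fs)
  x <- c(rep(0, fs), 0.5 * kern, rep(0, fs))
  one <- gsr_features(x, fs)
  expect_identical(one$no_of_peaks, 1L)
  expect_equal(one$GSR_min, one$GSR_max)
  expect_equal(one$GSR_avg, one$GSR_max)
  expect_equal(one$GSR_max, 0.5, tolerance = 0.1)
})

test_that("ECG features recover constant and alternating RR intervals", {
  fs <- 256
  # constant RR = 1000 ms
  rec <- session_recipe(seed = 21, duration_s = 30,
                        ecg = list(rr_sd_ms = 0, noise_sd = 0))
  set.seed(21)
  ecg <- gen_ecg(rec)
  f <- ecg_features(ecg$signal$samples, fs)
  expect_lt(abs(f$IBI_mean - 1000), 1000 / fs)
  expect_lt(f$IBI_var, 20)
  expect_lt(abs(f$HRV_mean), 8)
  # alternating 800/1200 ms
  beats <- cumsum(c(500, rep(c(800, 1200), 10)))
  n <- 256 * 25
  x <- numeric(n)
  tw <- seq(-0.06, 0.06, by = 1 / fs)
  template <- exp(-(tw / 0.012)^2)
  for (b in beats) {
    c0 <- round(b / 1000 * fs) + 1
    sel <- (c0 - 15):(c0 + 15); keep <- sel >= 1 & sel <= n
    x[sel[keep]] <- x[sel[keep]] + template[keep]
  }
  fa <- ecg_features(x, fs)
  expect_equal(fa$IBI_min, 800, tolerance = 0.01)
  expect_equal(fa$IBI_max, 1200, tolerance = 0.01)
  # flat line: nulls, not an error
  fn <- ecg_features(rep(0, 20 * fs), fs)
  expect_true(all(is.na(unlist(fn))))
})

test_that("mutual information matches the closed-form 4-sample cases", {
  ident <- mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1), bins = 2)
  expect_equal(ident$mi, 1, tolerance = 1e-12)
  expect_equal(ident$mi, ident$hx, tolerance = 1e-12)  # I(x,x) = H(x)
  expect_equal(ident$hy_given_x, 0, tolerance = 1e-12)
  indep <- mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1), bins = 2)
  expect_equal(indep$mi, 0, tolerance = 1e-12)
  expect_error(mutual_information(1:4, 1:5), class = "pg_length_mismatch")
})

test_that("mutual information is symmetric, non-negative and relabel-invariant", {
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(200); y <- 0.5 * x + rnorm(200)
    a <- mutual_information(x, y)
    b <- mutual_information(y, x)
    expect_lt(abs(a$mi - b$mi), 1e-12)
    expect_gte(a$mi, 0)
    expect_equal(a$mi, a$hy - a$hy_given_x, tolerance = 1e-12)
  }
  # invariance under strictly monotone relabeling of the bin indices
  x <- rnorm(500); y <- rnorm(500)
  ix <- physiograph:::discretize_bins(x, 8)
  iy <- physiograph:::discretize_bins(y, 8)
  base <- physiograph:::plugin_mi(ix, iy, 8)
  shifted <- physiograph:::plugin_mi(ix, 2L * iy + 3L, 2L * max(iy) + 3L)
  expect_equal(base$mi, shifted$mi, tolerance = 1e-12)
})

test_that("independent series stay below the permutation null", {
  set.seed(15)
  n <- 2000
  x <- runif(n); y <- runif(n)
  obs <- mutual_information(x, y)$mi
  bins <- min(16L, ceiling(sqrt(n)))
  ix <- physiograph:::discretize_bins(x, bins)
  iy <- physiograph:::discretize_bins(y, bins)
  null <- replicate(200, physiograph:::plugin_mi(ix, sample(iy), bins)$mi)
  expect_lt(obs, quantile(null, 0.95) + 1e-9)
})

test_that("calculators write node properties and same-epoch edges only", {
  set.seed(16)
  g <- build_electrode_graph(f = 8, t = 12, m = 3, te = 4)  # 3 epochs
  # m = 3, n = 3 epochs, no threshold -> n * m(m-1)/2 = 9 edges
  eids <- pg_match(g, label = "INFLUENCE_ON", what = "edges")
  expect_length(eids, 9)
  svs <- pg_match(g, label = "SignalValue")
  chains <- lapply(pg_match(g, label = "Measure"), function(m)
    physiograph:::measure_chain(g, m))
  epoch_of <- new.env()
  for (ch in chains) for (i in seq_len(nrow(ch)))
    epoch_of[[as.character(ch$id[i])]] <- ch$start_ms[i]
  for (eid in eids) {
    e <- pg_edge(g, eid)
    expect_identical(epoch_of[[as.character(e$source)]],
                     epoch_of[[as.character(e$target)]])
    expect_true(is.numeric(e$props$mi))
  }
  # edge direction: lexicographically smaller electrode name first
  ms <- pg_match(g, label = "Measure")
  name_of <- vapply(ms, function(m) pg_node(g, m)$props$name, character(1))
  sv_owner <- new.env()
  for (i in seq_along(ms)) {
    ch <- chains[[i]]
    for (j in seq_len(nrow(ch)))
      sv_owner[[as.character(ch$id[j])]] <- name_of[i]
  }
  for (eid in eids) {
    e <- pg_edge(g, eid)
    expect_true(sv_owner[[as.character(e$source)]] <
                  sv_owner[[as.character(e$target)]])
  }
})

test_that("an infinite threshold suppresses all influence edges", {
  set.seed(17)
  g <- pg_new()
  e <- create_experiment(g, "mu")
  h <- create_recording(g, e, create_participant(g, 1),
                        list(channel_spec("EEG")))
  lists <- lapply(1:2, function(i)
    list(spec = measure_spec(i, "electrode", c("A", "B")[i]),
         series = raw_signal(rnorm(64), 8)))
  import_signals(g, h, h$channels[1], lists, epoch_s = 4,
                 preprocess_cfg = FALSE)
  apply_calculators(g, calculator_job(
    h$channels[1], channel_measures(g, h$channels[1], "electrode"),
    rel_calcs = list(mi = function(x, y, fs) mutual_information(x, y)$mi),
    mu = Inf))
  expect_length(pg_match(g, label = "INFLUENCE_ON", what = "edges"), 0)
})
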