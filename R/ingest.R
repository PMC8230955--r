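# Ingestion: preprocessing, epoching and bulk import of raw sampled signals.
#
# A raw signal is a uniformly sampled series with rate f (Hz) and duration t
# (seconds). Fixed epoching of length te seconds yields floor(t / te) full
# epochs (trailing partial samples discarded); sliding windows of w samples
# with o samples overlap yield floor((f t - w) / (w - o)) windows, with any
# trailing window beyond that count discarded so construction and the
# closed-form sizing predictions agree exactly.

#' Construct a raw signal
#'
#' @param samples Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param channel_type Channel type string (`"EEG"`, `"ECG"`, `"GSR"`, ...).
#' @param measure_name Measure (electrode) name.
#' @return A `raw_signal` list with `samples`, `fs`, `duration_s`,
#'   `channel_type`, `measure_name`.
#' @export
raw_signal <- function(samples, fs, channel_type = NA_character_,
                       measure_name = NA_character_) {
  structure(list(samples = as.numeric(samples), fs = fs,
                 duration_s = length(samples) / fs,
                 channel_type = channel_type, measure_name = measure_name),
            class = "raw_signal")
}

#' Segment a signal into epochs or sliding windows
#'
#' Fixed mode (`epoch_s`) cuts consecutive non-overlapping epochs of
#' `epoch_s` seconds; sliding mode (`window = list(w, o)`, both in samples)
#' cuts overlapping windows whose starts advance by `w - o` samples.
#' Boundary times are integer milliseconds (sliding starts that fall between
#' milliseconds are rounded to the ms grid).
#'
#' @param sig A `raw_signal` (or numeric vector with `fs` given).
#' @param epoch_s Epoch length in seconds (fixed mode).
#' @param window `list(w = samples, o = overlap_samples)` (sliding mode).
#' @param fs Sampling rate when `sig` is a bare vector.
#' @return Data frame with `start_ms`, `end_ms` and a `samples` list column;
#'   zero rows when the signal is shorter than one epoch.
#' @export
epochize <- function(sig, epoch_s = NULL, window = NULL, fs = NULL) {
  if (inherits(sig, "raw_signal")) {
    x <- sig$samples; fs <- sig$fs
  } else {
    x <- as.numeric(sig)
    if (is.null(fs)) pg_abort("fs required for bare vectors",
                              "pg_invalid_params")
  }
  n <- length(x)
  if (is.null(epoch_s) == is.null(window))
    pg_abort("give exactly one of epoch_s or window", "pg_invalid_params")
  out <- list(); starts <- numeric(); ends <- numeric()
  if (!is.null(epoch_s)) {
    if (epoch_s <= 0) pg_abort("epoch_s must be positive", "pg_invalid_params")
    if (abs(epoch_s * 1000 - round(epoch_s * 1000)) > 1e-9)
      pg_abort("epoch_s must be a whole number of milliseconds",
               "pg_invalid_params")
    spp <- fs * epoch_s
    s <- floor(n / spp + 1e-12)
    for (k in seq_len(s)) {
      i0 <- floor((k - 1) * spp) + 1
      i1 <- floor(k * spp)
      out[[k]] <- x[i0:i1]
      starts <- c(starts, round((k - 1) * epoch_s * 1000))
      ends <- c(ends, round(k * epoch_s * 1000))
    }
  } else {
    w <- window$w; o <- window$o
    if (is.null(w) || is.null(o) || o < 0 || o >= w)
      pg_abort("sliding window requires 0 <= o < w", "pg_invalid_params")
    s <- max(0, floor((n - w) / (w - o)))
    for (k in seq_len(s)) {
      i0 <- (k - 1) * (w - o)
      out[[k]] <- x[(i0 + 1):(i0 + w)]
      starts <- c(starts, round(i0 / fs * 1000))
      ends <- c(ends, round((i0 + w) / fs * 1000))
    }
  }
  data.frame(start_ms = starts, end_ms = ends,
             samples = I(out))
}

#' Zero-phase filtering and resampling
#'
#' Band-limits and optionally resamples a raw signal. The filter is a
#' linear-phase windowed-sinc FIR applied forward and backward
#' ([signal::filtfilt()]), so the output is zero-phase and unconditionally
#' stable even for narrow bands. With all arguments `NULL` the signal is
#' returned unchanged.
#'
#' @param sig A `raw_signal`.
#' @param bpf_low_hz,bpf_high_hz Band edges in Hz; give both for a band-pass,
#'   only `bpf_high_hz` for a low-pass, only `bpf_low_hz` for a high-pass.
#' @param resample_hz Target rate in Hz (applied after filtering).
#' @param ntaps FIR length (odd); default adapts to signal length, capped
#'   at 513.
#' @return A filtered `raw_signal`.
#' @export
preprocess <- function(sig, bpf_low_hz = NULL, bpf_high_hz = NULL,
                       resample_hz = NULL, ntaps = NULL) {
  stopifnot(inherits(sig, "raw_signal"))
  x <- sig$samples; fs <- sig$fs
  nyq <- fs / 2
  for (f in c(bpf_low_hz, bpf_high_hz)) {
    if (!is.null(f) && f >= nyq)
      pg_abort("filter edge at or above Nyquist", "pg_nyquist_violation")
  }
  if (!is.null(bpf_low_hz) && !is.null(bpf_high_hz) &&
      bpf_low_hz >= bpf_high_hz)
    pg_abort("bpf_low_hz must be below bpf_high_hz", "pg_invalid_params")
  if (!is.null(bpf_low_hz) || !is.null(bpf_high_hz)) {
    if (is.null(ntaps)) ntaps <- min(513, 2 * floor(length(x) / 8) + 1)
    if (ntaps < 5) pg_abort("signal too short to filter", "pg_invalid_params")
    h <- if (!is.null(bpf_low_hz) && !is.null(bpf_high_hz))
      signal::fir1(ntaps - 1, c(bpf_low_hz, bpf_high_hz) / nyq, type = "pass")
    else if (!is.null(bpf_high_hz))
      signal::fir1(ntaps - 1, bpf_high_hz / nyq, type = "low")
    else
      signal::fir1(ntaps - 1, bpf_low_hz / nyq, type = "high")
    # mean-center to avoid start/end transients from the DC offset; restore
    # the level for a pure low-pass (band/high-pass remove DC anyway)
    mu <- mean(x)
    x <- signal::filtfilt(h, x - mu)  # fir1 returns an Ma object
    if (is.null(bpf_low_hz)) x <- x + mu
  }
  if (!is.null(resample_hz)) {
    if (resample_hz > fs * 8)
      pg_abort("upsampling by more than 8x not supported",
               "pg_invalid_params")
    rat <- ratio_approx(resample_hz / fs)
    x <- signal::resample(x, rat[1], rat[2])
    fs <- resample_hz
  }
  raw_signal(x, fs, sig$channel_type, sig$measure_name)
}

# small-denominator rational approximation for resampling ratios
ratio_approx <- function(r, max_den = 1024) {
  best <- c(1, 1); err <- Inf
  for (q in 1:max_den) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(p, q) }
    if (err < 1e-12) break
  }
  best
}

# channel-type preprocessing defaults: band edges bracket the analysis bands.
# skin conductance is deliberately left unfiltered: the SCR peak detector
# smooths internally, and acausal (zero-phase) low-passing smears response
# onsets across epoch boundaries, which corrupts per-epoch peak counts
default_preprocess_config <- function(channel_type) {
  switch(toupper(channel_type),
         EEG = list(bpf_low_hz = 0.5, bpf_high_hz = 45),
         ECG = list(bpf_low_hz = 0.5, bpf_high_hz = 40),
         list(bpf_low_hz = NULL, bpf_high_hz = NULL))
}

#' Import signal series onto a recording's channel
#'
#' For electrode measures the input is a raw sampled signal which is
#' (optionally) preprocessed, epoched, and stored as `data` arrays; all
#' electrode measures of one channel must produce identical epoch grids.
#' Epoch measures take `(start_ms, end_ms, value)` rows, timestamp measures
#' `(t_ms, value)` rows.
#'
#' @param g A `property_graph`.
#' @param handle A `recording_handle`.
#' @param channel Channel node id (one of `handle$channels`).
#' @param signal_lists List of `list(spec = measure_spec, series = ...)`
#'   pairs, where `series` is a `raw_signal` (electrode), a data frame with
#'   `start_ms`, `end_ms`, `value` (epoch), or a data frame with `t_ms`,
#'   `value` (timestamp).
#' @param epoch_s Fixed epoch length in seconds for electrode signals.
#' @param window Sliding-window spec `list(w, o)` (alternative to `epoch_s`).
#' @param preprocess_cfg `TRUE` for the channel-type default band limits,
#'   `FALSE`/`NULL` for none, or a list of [preprocess()] arguments.
#' @return Integer vector of created Measure node ids.
#' @export
import_signals <- function(g, handle, channel, signal_lists, epoch_s = NULL,
                           window = NULL, preprocess_cfg = TRUE) {
  ch_type <- pg_node(g, channel)$props$type
  tl <- timeline_init(g, handle$experiment)
  specs <- lapply(signal_lists, `[[`, "spec")
  # prepare everything (and validate epoch grids) before any mutation
  prepared <- vector("list", length(signal_lists))
  grid <- NULL
  for (i in seq_along(signal_lists)) {
    spec <- specs[[i]]; series <- signal_lists[[i]]$series
    if (spec$kind == "electrode") {
      if (!inherits(series, "raw_signal"))
        pg_abort("electrode measures take raw_signal input",
                 "pg_kind_mismatch")
      cfg <- if (isTRUE(preprocess_cfg)) default_preprocess_config(ch_type)
      else if (is.list(preprocess_cfg)) preprocess_cfg
      else list()
      if (length(cfg) && (!is.null(cfg$bpf_low_hz) ||
                          !is.null(cfg$bpf_high_hz) ||
                          !is.null(cfg$resample_hz)))
        series <- do.call(preprocess, c(list(series), cfg))
      ep <- epochize(series, epoch_s = epoch_s, window = window)
      if (is.null(grid)) grid <- ep[c("start_ms", "end_ms")]
      else if (!isTRUE(all.equal(grid, ep[c("start_ms", "end_ms")],
                                 check.attributes = FALSE)))
        pg_abort("electrode measures of one channel must share the epoch grid",
                 "pg_grid_mismatch")
      prepared[[i]] <- list(fs = series$fs, epochs = ep)
    } else {
      prepared[[i]] <- list(series = series)
    }
  }
  measures <- attach_measures(g, channel, specs)
  for (i in seq_along(signal_lists)) {
    spec <- specs[[i]]; m <- measures[i]
    if (spec$kind == "electrode") {
      ep <- prepared[[i]]$epochs
      pg_set_property(g, m, "fs", prepared[[i]]$fs)
      attach_epoch_values(tl, m, ep$start_ms, ep$end_ms, ep$samples,
                          allow_overlap = !is.null(window))
    } else if (spec$kind == "epoch") {
      series <- prepared[[i]]$series
      attach_epoch_values(tl, m, series$start_ms, series$end_ms,
                          as.list(series$value))
    } else {
      series <- prepared[[i]]$series
      attach_timestamp_values(tl, m, series$t_ms, series$value)
    }
  }
  measures
}

#' Read a signal CSV
#'
#' Three dialects: timestamp rows `t_ms,value`; epoch rows
#' `start_ms,end_ms,value` (or `v1;v2;...` payload in the third column);
#' raw rows `index,value` (sampling rate comes from the manifest).
#'
#' @param path CSV path.
#' @param kind `"timestamp"`, `"epoch"` or `"raw"`.
#' @param fs Sampling rate for raw dialect.
#' @return A data frame (`raw_signal` for the raw dialect).
#' @export
read_signal_csv <- function(path, kind = c("timestamp", "epoch", "raw"),
                            fs = NULL) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (kind == "timestamp") {
    data.frame(t_ms = df[[1]], value = df[[2]])
  } else if (kind == "epoch") {
    v <- df[[3]]
    if (is.character(v)) {
      payloads <- lapply(strsplit(v, ";", fixed = TRUE), as.numeric)
      single <- all(lengths(payloads) == 1)
      if (single) v <- vapply(payloads, `[[`, numeric(1), 1)
      else return(data.frame(start_ms = df[[1]], end_ms = df[[2]],
                             value = I(payloads)))
    }
    data.frame(start_ms = df[[1]], end_ms = df[[2]], value = v)
  } else {
    if (is.null(fs)) pg_abort("raw dialect requires fs", "pg_invalid_params")
    raw_signal(df[[2]], fs)
  }
}

#' Write a signal CSV
#'
#' Inverse of [read_signal_csv()]; numbers are written with full precision so
#' regeneration under a fixed seed is byte-identical.
#'
#' @param x A data frame or `raw_signal` as returned by the generators.
#' @param path Output path.
#' @param kind Dialect (see [read_signal_csv()]).
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path, kind = c("timestamp", "epoch", "raw")) {
  kind <- match.arg(kind)
  fmt <- function(v) formatC(v, digits = 10, format = "g")
  lines <- if (kind == "timestamp") {
    c("t_ms,value", paste(fmt(x$t_ms), fmt(x$value), sep = ","))
  } else if (kind == "epoch") {
    vals <- if (is.list(x$value))
      vapply(x$value, function(p) paste(fmt(p), collapse = ";"), character(1))
    else fmt(x$value)
    c("start_ms,end_ms,value",
      paste(fmt(x$start_ms), fmt(x$end_ms), vals, sep = ","))
  } else {
    s <- if (inherits(x, "raw_signal")) x$samples else x
    c("index,value", paste(seq_along(s) - 1, fmt(s), sep = ","))
  }
  writeLines(lines, path)
  invisible(path)
}
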