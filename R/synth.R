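# Seeded synthetic session generators with known ground truth.
#
# These generators exist to make every pipeline stage testable without any
# external recording: EEG as band-limited sinusoid mixtures plus noise (with
# an optional component shared between electrodes to induce mutual
# information), ECG as an R-spike template placed at beat times with
# Gaussian R-R variability, skin conductance as a tonic level with injected
# SCR-shaped bumps, and piecewise-constant valence/arousal annotations. No
# physiological realism is claimed; the point is recoverable ground truth.

#' Standard 14-electrode montage (10-20 names)
#'
#' @return Character vector of 14 scalp electrode names.
#' @export
electrodes_1020_14 <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
}

#' Describe a synthetic session
#'
#' Defaults describe the standard study condition: a 120 s recording with a
#' 14-electrode EEG at 128 Hz, a left/right ECG at 256 Hz with
#' R-R ~ N(1000, 50^2) ms, one skin-conductance electrode at 32 Hz with
#' SCR bumps of amplitude 0.5, valence/arousal annotations on a 20 s epoch
#' grid, and 20 s analysis epochs.
#'
#' @param seed Integer seed; the whole session is a deterministic function
#'   of it.
#' @param duration_s Recording length in seconds.
#' @param epoch_s Analysis epoch length in seconds.
#' @param eeg,ecg,gsr,annotations Per-modality parameter lists; see the
#'   defaults in the function body. Set a modality to `NULL` to omit it.
#' @return A `session_recipe` list.
#' @export
session_recipe <- function(seed = 1, duration_s = 120, epoch_s = 20,
                           eeg = list(), ecg = list(), gsr = list(),
                           annotations = list()) {
  merge_defaults <- function(x, d) {
    if (is.null(x)) return(NULL)
    d[names(x)] <- x
    d
  }
  structure(list(
    seed = seed, duration_s = duration_s, epoch_s = epoch_s,
    eeg = merge_defaults(eeg, list(
      electrodes = electrodes_1020_14(), fs = 128,
      band_amps = c(delta = 2, theta = 1.5, alpha = 3, beta = 1, gamma = 0.5),
      noise_sd = 1, shared_weight = 0.7)),
    ecg = merge_defaults(ecg, list(
      fs = 256, rr_mean_ms = 1000, rr_sd_ms = 50, noise_sd = 0.01)),
    gsr = merge_defaults(gsr, list(
      fs = 32, peak_times_s = NULL, peak_amp = 0.5, tonic = 1,
      noise_sd = 0.002)),
    annotations = merge_defaults(annotations, list(
      model = "russell", kind = "epoch", fs = 1, value_range = c(-1, 1)))
  ), class = "session_recipe")
}

band_center_freqs <- c(delta = 2, theta = 6, alpha = 10, beta = 20,
                       gamma = 40)

#' Generate synthetic EEG signals
#'
#' Each electrode is a sum of sinusoids at the five band-center frequencies
#' (2, 6, 10, 20, 40 Hz) with the recipe's amplitudes and random phases,
#' plus white noise. A `shared_weight` > 0 adds one common noise component
#' to every electrode so electrode pairs carry nonzero mutual information.
#'
#' @param recipe A [session_recipe()] (its `eeg` entry is used). The caller
#'   is responsible for seeding; [gen_session()] seeds once per session.
#' @return List with `signals` (list of `raw_signal`, one per electrode)
#'   and `truth` (`dominant_band` per electrode).
#' @export
gen_eeg <- function(recipe) {
  cfg <- recipe$eeg
  fs <- cfg$fs; n <- round(recipe$duration_s * fs)
  active <- names(cfg$band_amps)[cfg$band_amps > 0]
  if (length(active) && fs <= 2 * max(band_center_freqs[active]))
    pg_abort("sampling rate below twice the highest generated frequency",
             "pg_nyquist_violation")
  tt <- (0:(n - 1)) / fs
  shared <- stats::rnorm(n)
  signals <- list()
  dominant <- character()
  for (el in cfg$electrodes) {
    x <- numeric(n)
    for (b in names(cfg$band_amps)) {
      a <- cfg$band_amps[[b]]
      if (a == 0) next
      x <- x + a * sin(2 * pi * band_center_freqs[[b]] * tt +
                         stats::runif(1, 0, 2 * pi))
    }
    x <- x + cfg$noise_sd * stats::rnorm(n) + cfg$shared_weight * shared
    signals[[el]] <- raw_signal(x, fs, "EEG", el)
    amps <- cfg$band_amps
    dominant[el] <- if (all(amps == 0)) NA_character_
    else names(amps)[which.max(amps)]
  }
  list(signals = signals, truth = list(dominant_band = dominant))
}

#' Generate a synthetic ECG signal
#'
#' Beats are placed at cumulative R-R intervals drawn from
#' N(`rr_mean_ms`, `rr_sd_ms`^2) truncated at 300 ms; each beat is a narrow
#' positive R spike with small flanking negative lobes.
#'
#' @param recipe A [session_recipe()].
#' @return List with `signal` (`raw_signal`) and `truth`
#'   (`beat_times_ms`).
#' @export
gen_ecg <- function(recipe) {
  cfg <- recipe$ecg
  if (cfg$rr_mean_ms <= 300)
    pg_abort("rr_mean_ms must exceed 300 ms", "pg_invalid_rr")
  fs <- cfg$fs; n <- round(recipe$duration_s * fs)
  beats <- numeric(); tcur <- 500
  repeat {
    if (tcur > recipe$duration_s * 1000 - 200) break
    beats <- c(beats, tcur)
    rr <- stats::rnorm(1, cfg$rr_mean_ms, cfg$rr_sd_ms)
    tcur <- tcur + max(300, rr)
  }
  # R spike template: positive Gaussian with small negative side lobes
  tw <- seq(-0.06, 0.06, by = 1 / fs)
  template <- exp(-(tw / 0.012)^2) - 0.15 * exp(-((tw - 0.03) / 0.02)^2) -
    0.1 * exp(-((tw + 0.03) / 0.02)^2)
  x <- numeric(n)
  half <- (length(template) - 1) / 2
  for (b in beats) {
    c0 <- round(b / 1000 * fs) + 1
    lo <- c0 - half; hi <- c0 + half
    sel <- lo:hi
    keep <- sel >= 1 & sel <= n
    x[sel[keep]] <- x[sel[keep]] + template[keep]
  }
  x <- x + cfg$noise_sd * stats::rnorm(n)
  list(signal = raw_signal(x, fs, "ECG", NA_character_),
       truth = list(beat_times_ms = beats))
}

# SCR kernel: difference of exponentials, 0.75 s rise, 2 s decay, unit peak
scr_kernel <- function(fs, span_s = 10) {
  tt <- seq(0, span_s, by = 1 / fs)
  k <- exp(-tt / 2) - exp(-tt / 0.75)
  k / max(k)
}

#' Generate a synthetic skin-conductance signal
#'
#' A constant tonic level plus SCR-shaped bumps (difference of exponentials,
#' 0.75 s rise, 2 s decay) at the recipe's peak times, plus small noise.
#' Default peak times place one bump every 15 s starting at 5 s.
#'
#' @param recipe A [session_recipe()].
#' @return List with `signal` and `truth` (`peak_times_s`, and
#'   `peaks_per_epoch` for the recipe's epoch grid).
#' @export
gen_gsr <- function(recipe) {
  cfg <- recipe$gsr
  fs <- cfg$fs; n <- round(recipe$duration_s * fs)
  pk <- cfg$peak_times_s
  if (is.null(pk)) pk <- seq(5, recipe$duration_s - 5, by = 15)
  pk <- pk[pk > 0 & pk < recipe$duration_s]
  x <- rep(cfg$tonic, n)
  kern <- scr_kernel(fs)
  for (p in pk) {
    i0 <- round(p * fs) + 1
    sel <- i0:min(n, i0 + length(kern) - 1)
    x[sel] <- x[sel] + cfg$peak_amp * kern[seq_along(sel)]
  }
  x <- x + cfg$noise_sd * stats::rnorm(n)
  nep <- floor(recipe$duration_s / recipe$epoch_s)
  per_epoch <- vapply(seq_len(nep), function(k)
    sum(pk >= (k - 1) * recipe$epoch_s & pk < k * recipe$epoch_s),
    integer(1))
  list(signal = raw_signal(x, fs, "GSR", "GSR"),
       truth = list(peak_times_s = pk, peaks_per_epoch = per_epoch))
}

#' Generate annotation streams
#'
#' Valence and arousal are piecewise constant per analysis epoch, drawn
#' uniformly from the recipe's value range. Depending on `kind` the output
#' is either per-epoch rows (`start_ms,end_ms,value`) or a timestamp stream
#' sampled at `fs` Hz from the underlying step function (the heterogeneous
#' annotation-rate case: the epoch average then equals the step value
#' regardless of the rate).
#'
#' @param recipe A [session_recipe()].
#' @return List with `valence` and `arousal` data frames and `truth`
#'   (the per-epoch values).
#' @export
gen_annotations <- function(recipe) {
  cfg <- recipe$annotations
  nep <- floor(recipe$duration_s / recipe$epoch_s)
  vals <- list(
    valence = stats::runif(nep, cfg$value_range[1], cfg$value_range[2]),
    arousal = stats::runif(nep, cfg$value_range[1], cfg$value_range[2]))
  out <- list()
  for (nm in names(vals)) {
    if (cfg$kind == "epoch") {
      out[[nm]] <- data.frame(
        start_ms = (seq_len(nep) - 1) * recipe$epoch_s * 1000,
        end_ms = seq_len(nep) * recipe$epoch_s * 1000,
        value = vals[[nm]])
    } else {
      step <- 1000 / cfg$fs
      t_ms <- seq(0, recipe$duration_s * 1000 - step, by = step)
      ep <- pmin(nep, floor(t_ms / 1000 / recipe$epoch_s) + 1)
      out[[nm]] <- data.frame(t_ms = t_ms, value = vals[[nm]][ep])
    }
  }
  out$truth <- vals
  out
}

#' Generate a complete on-disk synthetic session
#'
#' Seeds the generator, produces all modalities of the recipe, writes one
#' CSV per measure plus a YAML manifest into `dir`, and returns the ground
#' truth. Regeneration with the same recipe is byte-identical.
#'
#' @param recipe A [session_recipe()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `manifest` (path) and `truth`.
#' @export
gen_session <- function(recipe = session_recipe(), dir = tempfile("session")) {
  set.seed(recipe$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    experiment = list(name = sprintf("synthetic-%d", recipe$seed)),
    participant = list(user_id = 1),
    duration_s = recipe$duration_s,
    epoch_s = recipe$epoch_s,
    channels = list()
  )
  truth <- list()
  sid <- 0
  next_sid <- function() { sid <<- sid + 1; sid }

  if (!is.null(recipe$eeg)) {
    eeg <- gen_eeg(recipe)
    measures <- list()
    for (el in names(eeg$signals)) {
      f <- sprintf("eeg_%s.csv", el)
      write_signal_csv(eeg$signals[[el]], file.path(dir, f), kind = "raw")
      measures[[length(measures) + 1]] <-
        list(signal_id = next_sid(), name = el, file = f)
    }
    manifest$channels[[length(manifest$channels) + 1]] <- list(
      type = "EEG", recording_standard = "10-20", kind = "electrode",
      fs = recipe$eeg$fs, dialect = "raw", measures = measures)
    truth$eeg <- eeg$truth
  }
  if (!is.null(recipe$ecg)) {
    measures <- list()
    truth$ecg <- list()
    for (el in c("left", "right")) {
      ecg <- gen_ecg(recipe)
      f <- sprintf("ecg_%s.csv", el)
      write_signal_csv(ecg$signal, file.path(dir, f), kind = "raw")
      measures[[length(measures) + 1]] <-
        list(signal_id = next_sid(), name = el, file = f)
      truth$ecg[[el]] <- ecg$truth
    }
    manifest$channels[[length(manifest$channels) + 1]] <- list(
      type = "ECG", kind = "electrode", fs = recipe$ecg$fs,
      dialect = "raw", measures = measures)
  }
  if (!is.null(recipe$gsr)) {
    gsr <- gen_gsr(recipe)
    f <- "gsr.csv"
    write_signal_csv(gsr$signal, file.path(dir, f), kind = "raw")
    manifest$channels[[length(manifest$channels) + 1]] <- list(
      type = "GSR", kind = "electrode", fs = recipe$gsr$fs,
      dialect = "raw",
      measures = list(list(signal_id = next_sid(), name = "GSR", file = f)))
    truth$gsr <- gsr$truth
  }
  if (!is.null(recipe$annotations)) {
    ann <- gen_annotations(recipe)
    kind <- recipe$annotations$kind
    measures <- list()
    for (nm in c("valence", "arousal")) {
      f <- sprintf("%s.csv", nm)
      write_signal_csv(ann[[nm]], file.path(dir, f),
                       kind = if (kind == "epoch") "epoch" else "timestamp")
      measures[[length(measures) + 1]] <- list(
        signal_id = next_sid(), name = nm, datatype = "float",
        range = sprintf("%g..%g inclusive",
                        recipe$annotations$value_range[1],
                        recipe$annotations$value_range[2]),
        file = f)
    }
    manifest$channels[[length(manifest$channels) + 1]] <- list(
      type = "Annotation", kind = kind,
      fs = if (kind == "timestamp") recipe$annotations$fs else NULL,
      dialect = if (kind == "epoch") "epoch" else "timestamp",
      measures = measures)
    truth$annotations <- ann$truth
  }
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(dir = dir, manifest = manifest_path, truth = truth))
}

#' Ingest a session directory into a new graph
#'
#' Reads the manifest, creates the experiment, participant, recording and
#' channels, imports every declared measure, and epochs electrode signals on
#' the manifest's epoch grid.
#'
#' @param dir Session directory containing `manifest.yaml` (as written by
#'   [gen_session()]).
#' @param preprocess_cfg Passed to [import_signals()] (default: channel-type
#'   band limits).
#' @return List with `g` (the graph), `handle` (the `recording_handle`) and
#'   `manifest`.
#' @export
ingest_session <- function(dir, preprocess_cfg = TRUE) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  g <- pg_new()
  exp_id <- create_experiment(g, manifest$experiment$name)
  part <- create_participant(g, manifest$participant$user_id)
  chspecs <- lapply(manifest$channels, function(ch)
    channel_spec(ch$type, ch$recording_standard))
  handle <- create_recording(g, exp_id, part, chspecs)
  for (i in seq_along(manifest$channels)) {
    ch <- manifest$channels[[i]]
    lists <- lapply(ch$measures, function(ms) {
      spec <- measure_spec(ms$signal_id,
                           kind = if (ch$kind == "electrode") "electrode"
                           else ch$kind,
                           name = ms$name, datatype = ms$datatype,
                           range = ms$range,
                           fs = ch$fs)
      series <- read_signal_csv(file.path(dir, ms$file),
                                kind = ch$dialect, fs = ch$fs)
      list(spec = spec, series = series)
    })
    import_signals(g, handle, handle$channels[i], lists,
                   epoch_s = if (ch$kind == "electrode") manifest$epoch_s
                   else NULL,
                   preprocess_cfg = preprocess_cfg)
  }
  list(g = g, handle = handle, manifest = manifest)
}

#' Average a timestamp series over an epoch grid
#'
#' Utility for unifying heterogeneous-rate annotation streams onto a common
#' epoch length: each epoch's value is the mean of the samples whose times
#' fall in `[start, end)`.
#'
#' @param t_ms,value Timestamp series.
#' @param epoch_ms Epoch length in milliseconds.
#' @param duration_ms Total span (defaults to the last sample time + 1).
#' @return Data frame `start_ms`, `end_ms`, `value`.
#' @export
epoch_average <- function(t_ms, value, epoch_ms,
                          duration_ms = max(t_ms) + 1) {
  nep <- floor(duration_ms / epoch_ms)
  starts <- (seq_len(nep) - 1) * epoch_ms
  vals <- vapply(seq_len(nep), function(k) {
    sel <- t_ms >= starts[k] & t_ms < starts[k] + epoch_ms
    if (any(sel)) mean(value[sel]) else NA_real_
  }, numeric(1))
  data.frame(start_ms = starts, end_ms = starts + epoch_ms, value = vals)
}
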