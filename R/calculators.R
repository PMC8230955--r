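# Per-channel feature calculators.
#
# Node calculators map one epoch's sample array to a named property list
# written onto the SignalValue node; relationship calculators map two
# same-epoch sample arrays to a scalar stored on an INFLUENCE_ON edge.
# Defaults: EEG -> multitaper band power (node) + mutual information (rel);
# ECG -> interbeat-interval and heart-rate-variability statistics;
# GSR -> skin-conductance peak summaries.

#' Canonical EEG frequency bands
#'
#' Half-open intervals `[low, high)` so the shared printed boundaries
#' (4, 8, 12, 30 Hz) belong to exactly one band: delta 0.5-4, theta 4-8,
#' alpha 8-12, beta 12-30, gamma 30-100 Hz.
#'
#' @return Data frame with `name`, `low_hz`, `high_hz`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low_hz = c(0.5, 4, 8, 12, 30),
             high_hz = c(4, 8, 12, 30, 100))
}

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` Slepian sequences for length `n` and
#' time-bandwidth product `nw` from the standard symmetric tridiagonal
#' eigenproblem. For `n` above 512 the tapers are computed at length 512 and
#' spline-interpolated to `n` (then renormalized); eigenvalue concentrations
#' are evaluated on the final tapers by integrating the squared spectrum over
#' the concentration band via a zero-padded FFT.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 4).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return List with `tapers` (n x k matrix, unit-energy columns) and
#'   `eigen` (concentration ratios in (0, 1]).
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  nref <- min(n, 512L)
  w <- nw / nref
  i <- 0:(nref - 1)
  diag_v <- ((nref - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off_v <- (1:(nref - 1)) * (nref - 1:(nref - 1)) / 2
  m <- diag(diag_v)
  m[cbind(1:(nref - 1), 2:nref)] <- off_v
  m[cbind(2:nref, 1:(nref - 1))] <- off_v
  es <- eigen(m, symmetric = TRUE)
  tap <- es$vectors[, seq_len(k), drop = FALSE]
  if (n > nref) {
    xs <- seq(0, 1, length.out = nref)
    xt <- seq(0, 1, length.out = n)
    tap <- apply(tap, 2, function(v) stats::spline(xs, v, xout = xt)$y)
  }
  # unit energy; fix sign: symmetric tapers positive mean, others positive slope
  for (j in seq_len(k)) {
    v <- tap[, j] / sqrt(sum(tap[, j]^2))
    s <- sum(v)
    if (abs(s) > 1e-7) { if (s < 0) v <- -v }
    else if (v[2] - v[1] < 0) v <- -v
    tap[, j] <- v
  }
  # concentrations on the final length-n tapers
  wn <- nw / n
  nfft <- 2^ceiling(log2(8 * n))
  freqs <- (0:(nfft - 1)) / nfft
  inband <- freqs <= wn | freqs >= 1 - wn
  eig <- apply(tap, 2, function(v) {
    p <- Mod(stats::fft(c(v, rep(0, nfft - n))))^2
    sum(p[inband]) / sum(p)
  })
  res <- list(tapers = tap, eigen = eig)
  .dpss_cache[[key]] <- res
  res
}

#' Thomson multitaper power spectral density
#'
#' Eigenvalue-weighted average of the `k` Slepian-tapered periodograms (the
#' weighting compensates the energy loss of higher-order tapers). One-sided,
#' normalized so that summing `psd * df` over all frequencies approximates
#' the signal's mean square.
#'
#' @param x Numeric samples (one epoch).
#' @param fs Sampling rate in Hz.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers.
#' @return List with `freq` (Hz) and `psd`.
#' @export
multitaper_psd <- function(x, fs, nw = 4, k = 2 * nw - 1) {
  n <- length(x)
  if (n < 2 * k) pg_abort("epoch too short for multitaper estimation",
                          "pg_epoch_too_short")
  dp <- dpss_tapers(n, nw, k)
  nhalf <- floor(n / 2) + 1
  acc <- numeric(nhalf)
  for (j in seq_len(k)) {
    s <- Mod(stats::fft(x * dp$tapers[, j]))^2
    acc <- acc + dp$eigen[j] * s[seq_len(nhalf)]
  }
  s_avg <- acc / sum(dp$eigen)
  # fold the negative frequencies into the one-sided estimate
  fold <- rep(2, nhalf); fold[1] <- 1
  if (n %% 2 == 0) fold[nhalf] <- 1
  psd <- s_avg * fold / fs
  list(freq = (seq_len(nhalf) - 1) * fs / n, psd = psd)
}

#' EEG band power via the multitaper method
#'
#' Integrates the multitaper PSD over each named band (half-open intervals,
#' clipped at Nyquist).
#'
#' @param x Numeric samples (one epoch).
#' @param fs Sampling rate in Hz.
#' @param bands Band table as from [default_bands()].
#' @param nw,k Multitaper parameters.
#' @return Named list of band powers (`delta` ... `gamma`).
#' @export
eeg_bandpower <- function(x, fs, bands = default_bands(), nw = 4,
                          k = 2 * nw - 1) {
  if (length(x) == 0) pg_abort("empty epoch", "pg_epoch_too_short")
  if (all(x == 0)) {
    out <- as.list(rep(0, nrow(bands)))
    names(out) <- bands$name
    return(out)
  }
  est <- multitaper_psd(x, fs, nw, k)
  df <- fs / length(x)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    hi <- min(bands$high_hz[i], fs / 2 + df / 2)
    sel <- est$freq >= bands$low_hz[i] & est$freq < hi
    sum(est$psd[sel]) * df
  })
  names(out) <- bands$name
  out
}

#' Skin-conductance peak features
#'
#' Detects phasic skin-conductance responses by smoothing the epoch,
#' locating onsets at upward zero-crossings of the derivative, and accepting
#' a peak when the rise from onset to the local maximum exceeds
#' `amp_threshold`. Peak amplitude is the rise above its onset value.
#'
#' @param x Numeric samples (one epoch of skin conductance).
#' @param fs Sampling rate in Hz.
#' @param amp_threshold Minimum onset-to-peak rise counted as a peak
#'   (default 0.01 signal units).
#' @param smooth_s Moving-average smoothing window in seconds.
#' @return List with `GSR_min`, `GSR_max`, `GSR_avg` (statistics over the
#'   detected peak amplitudes; `NA` when no peak) and `no_of_peaks`.
#' @export
gsr_features <- function(x, fs, amp_threshold = 0.01, smooth_s = 0.25) {
  if (length(x) == 0) pg_abort("empty epoch", "pg_epoch_too_short")
  wlen <- max(1, round(fs * smooth_s))
  xs <- if (wlen > 1 && length(x) > wlen)
    as.numeric(stats::filter(x, rep(1 / wlen, wlen), sides = 2)) else x
  xs[is.na(xs)] <- x[is.na(xs)]
  d <- diff(xs)
  amps <- numeric()
  i <- 1
  n <- length(d)
  while (i <= n) {
    if (d[i] > 0 && (i == 1 || d[i - 1] <= 0)) {
      j <- i
      while (j <= n && d[j] > 0) j <- j + 1
      rise <- xs[j] - xs[i]
      if (!is.na(rise) && rise >= amp_threshold) amps <- c(amps, rise)
      i <- j
    }
    i <- i + 1
  }
  if (length(amps) == 0)
    list(GSR_min = NA_real_, GSR_max = NA_real_, GSR_avg = NA_real_,
         no_of_peaks = 0L)
  else
    list(GSR_min = min(amps), GSR_max = max(amps), GSR_avg = mean(amps),
         no_of_peaks = length(amps))
}

# R-peak detection: differentiate-square-smooth with adaptive threshold and
# refractory period, peak refined to the local maximum of the raw signal.
detect_r_peaks <- function(x, fs, refractory_s = 0.2, threshold_frac = 0.5) {
  n <- length(x)
  if (n < 8 || max(x) - min(x) < 1e-12) return(integer())
  lag <- max(1, round(0.016 * fs))  # ~16 ms differentiator span
  d <- c(rep(0, lag), x[(lag + 1):n] - x[1:(n - lag)])
  y <- d^2
  wlen <- max(1, round(0.048 * fs))
  y <- as.numeric(stats::filter(y, rep(1 / wlen, wlen), sides = 2))
  y[is.na(y)] <- 0
  thr <- threshold_frac * stats::quantile(y, 0.995, names = FALSE)
  if (thr <= 0) return(integer())
  refr <- round(refractory_s * fs)
  half <- max(1, round(0.04 * fs))
  peaks <- integer()
  i <- 1
  while (i <= n) {
    if (y[i] > thr) {
      j <- i
      while (j < n && y[j + 1] > thr) j <- j + 1
      lo <- max(1, i - half); hi <- min(n, j + half)
      p <- lo + which.max(x[lo:hi]) - 1
      if (length(peaks) == 0 || p - peaks[length(peaks)] >= refr)
        peaks <- c(peaks, p)
      i <- j + refr
    }
    i <- i + 1
  }
  peaks
}

#' ECG interbeat-interval and heart-rate-variability features
#'
#' R-peaks are located with a differentiated, squared and smoothed detection
#' signal under an adaptive threshold with a 200 ms refractory period, the
#' peak refined to the raw-signal maximum. IBI is the series of successive
#' R-R intervals in milliseconds; HRV is the series of successive IBI
#' differences. Each series is summarized by its minimum, maximum, variance
#' and mean (eight values). Fewer than three detected beats yield all-`NA`
#' features rather than an error, supporting missing values downstream.
#'
#' @param x Numeric samples (one ECG epoch).
#' @param fs Sampling rate in Hz.
#' @param refractory_s Refractory period in seconds.
#' @param threshold_frac Threshold as a fraction of the detection signal's
#'   99.5th percentile.
#' @return Named list `HRV_min/max/var/mean`, `IBI_min/max/var/mean`.
#' @export
ecg_features <- function(x, fs, refractory_s = 0.2, threshold_frac = 0.5) {
  nulls <- list(HRV_min = NA_real_, HRV_max = NA_real_, HRV_var = NA_real_,
                HRV_mean = NA_real_, IBI_min = NA_real_, IBI_max = NA_real_,
                IBI_var = NA_real_, IBI_mean = NA_real_)
  if (length(x) == 0) pg_abort("empty epoch", "pg_epoch_too_short")
  peaks <- detect_r_peaks(x, fs, refractory_s, threshold_frac)
  if (length(peaks) < 3) return(nulls)
  ibi <- diff(peaks) / fs * 1000
  hrv <- diff(ibi)
  list(HRV_min = min(hrv), HRV_max = max(hrv),
       HRV_var = if (length(hrv) > 1) stats::var(hrv) else 0,
       HRV_mean = mean(hrv),
       IBI_min = min(ibi), IBI_max = max(ibi),
       IBI_var = if (length(ibi) > 1) stats::var(ibi) else 0,
       IBI_mean = mean(ibi))
}

#' Histogram-based mutual information
#'
#' Discretizes both series with equal-width bins over each series' observed
#' range and computes the maximum-likelihood (plug-in) entropies from the
#' joint histogram, in bits. The estimate is I(X;Y) = H(Y) - H(Y|X).
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @param bins Number of bins per axis; default `ceiling(sqrt(n))` capped
#'   at 16.
#' @return An `mi_estimate`: list with `mi`, `hx`, `hy`, `hy_given_x`
#'   (bits) and `bins`.
#' @export
mutual_information <- function(x, y, bins = NULL) {
  n <- length(x)
  if (length(y) != n) pg_abort("x and y must have equal length",
                               "pg_length_mismatch")
  if (n < 2) pg_abort("need at least two samples", "pg_length_mismatch")
  if (is.null(bins)) bins <- min(16L, ceiling(sqrt(n)))
  ix <- discretize_bins(x, bins)
  iy <- discretize_bins(y, bins)
  plugin_mi(ix, iy, bins)
}

discretize_bins <- function(x, bins) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps * 10) return(rep(1L, length(x)))
  pmin(bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * bins))
}

plugin_entropy <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

plugin_mi <- function(ix, iy, bins) {
  n <- length(ix)
  hx <- plugin_entropy(tabulate(ix, bins), n)
  hy <- plugin_entropy(tabulate(iy, bins), n)
  hxy <- plugin_entropy(tabulate(ix + (iy - 1L) * bins, bins * bins), n)
  mi <- hx + hy - hxy
  if (mi < 0 && mi > -1e-12) mi <- 0
  structure(list(mi = mi, hx = hx, hy = hy, hy_given_x = hxy - hx,
                 bins = bins),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> I = %.4f bits (H(X) = %.4f, H(Y) = %.4f, H(Y|X) = %.4f, %d bins)\n",
              x$mi, x$hx, x$hy, x$hy_given_x, x$bins))
  invisible(x)
}

#' Default calculator registry
#'
#' Node calculators are functions `(samples, fs) -> named list` written as
#' SignalValue properties; relationship calculators are functions
#' `(samples_x, samples_y, fs) -> scalar` stored on INFLUENCE_ON edges under
#' the calculator's name.
#'
#' @return Nested list keyed by channel type with `node` and `rel` entries.
#' @export
calculator_registry <- function() {
  list(
    EEG = list(
      node = list(bandpower = function(x, fs) eeg_bandpower(x, fs)),
      rel = list(mi = function(x, y, fs) mutual_information(x, y)$mi)
    ),
    ECG = list(
      node = list(hrv = function(x, fs) ecg_features(x, fs)),
      rel = list()
    ),
    GSR = list(
      node = list(scr = function(x, fs) gsr_features(x, fs)),
      rel = list()
    )
  )
}

#' Describe a calculator job
#'
#' @param channel Channel node id.
#' @param measures Electrode measure node ids (the set U of m measures, all
#'   on one channel with a shared epoch grid).
#' @param node_calcs Named list of node calculators.
#' @param rel_calcs Named list of relationship calculators.
#' @param mu Optional threshold: an INFLUENCE_ON edge is created only when
#'   the calculated value is `>= mu`; with `mu = NULL` every same-epoch pair
#'   gets an edge.
#' @return A `calculator_job` list.
#' @export
calculator_job <- function(channel, measures, node_calcs = list(),
                           rel_calcs = list(), mu = NULL) {
  structure(list(channel = channel, measures = as.integer(measures),
                 node_calcs = node_calcs, rel_calcs = rel_calcs, mu = mu),
            class = "calculator_job")
}

#' Apply calculators to a channel's signal network
#'
#' Node calculators write their properties onto every SignalValue of every
#' measure in the job. Relationship calculators create INFLUENCE_ON edges
#' between same-epoch SignalValue pairs of different measures (Cartesian
#' pairing: never across epochs), directed from the lexicographically
#' smaller electrode name to the larger, carrying the calculated value; with
#' a threshold, only pairs whose value reaches it get an edge.
#'
#' @param g A `property_graph`.
#' @param job A [calculator_job()].
#' @return The graph, invisibly.
#' @export
apply_calculators <- function(g, job) {
  ms <- job$measures
  if (length(ms) == 0) return(invisible(g))
  chains <- lapply(ms, function(m) measure_chain(g, m))
  nep <- unique(vapply(chains, nrow, integer(1)))
  if (length(nep) != 1)
    pg_abort("measures have unequal epoch counts", "pg_grid_mismatch")
  if (nep > 0 && length(ms) > 1) {
    ref <- chains[[1]][c("start_ms", "end_ms")]
    for (i in 2:length(ms)) {
      if (!isTRUE(all.equal(ref, chains[[i]][c("start_ms", "end_ms")],
                            check.attributes = FALSE)))
        pg_abort("measures do not share the epoch grid", "pg_grid_mismatch")
    }
  }
  fss <- vapply(ms, function(m)
    as.numeric(pg_node(g, m)$props$fs %||% NA_real_), numeric(1))
  get_data <- function(mi, ei) {
    p <- pg_node(g, chains[[mi]]$id[ei])$props
    if (!is.null(p$data)) p$data else p$value
  }
  for (mi in seq_along(ms)) {
    for (ei in seq_len(nep)) {
      dat <- get_data(mi, ei)
      if (is.null(dat)) next
      for (cname in names(job$node_calcs)) {
        res <- job$node_calcs[[cname]](dat, fss[mi])
        for (pn in names(res))
          pg_set_property(g, chains[[mi]]$id[ei], pn, res[[pn]])
      }
    }
  }
  if (length(job$rel_calcs) && length(ms) > 1) {
    enames <- vapply(ms, function(m)
      as.character(pg_node(g, m)$props$name %||% ""), character(1))
    ord <- order(enames)
    for (a in seq_len(length(ms) - 1)) {
      for (b in (a + 1):length(ms)) {
        mi <- ord[a]; mj <- ord[b]  # smaller electrode name first
        for (ei in seq_len(nep)) {
          xa <- get_data(mi, ei); xb <- get_data(mj, ei)
          eid <- NULL
          for (cname in names(job$rel_calcs)) {
            val <- if (is.null(xa) || is.null(xb)) NA_real_
            else job$rel_calcs[[cname]](xa, xb, fss[mi])
            if (!is.null(job$mu) && (is.na(val) || val < job$mu)) next
            if (is.null(eid))
              eid <- pg_create_edge(g, chains[[mi]]$id[ei],
                                    chains[[mj]]$id[ei], "INFLUENCE_ON")
            if (!is.na(val)) pg_set_property(g, eid, cname, val,
                                             element = "edge")
          }
        }
      }
    }
  }
  invisible(g)
}

#' Run the registered calculators for one channel
#'
#' Looks up the channel's type in the registry, assembles the
#' [calculator_job()] from its electrode measures and applies it.
#'
#' @param g A `property_graph`.
#' @param channel Channel node id.
#' @param mu Optional relationship threshold.
#' @param registry Calculator registry (default [calculator_registry()]).
#' @return The graph, invisibly.
#' @export
apply_channel_calculators <- function(g, channel, mu = NULL,
                                      registry = calculator_registry()) {
  ch_type <- pg_node(g, channel)$props$type
  calcs <- registry[[ch_type]]
  if (is.null(calcs)) return(invisible(g))
  ms <- channel_measures(g, channel, kind = "electrode")
  if (length(ms) == 0) return(invisible(g))
  apply_calculators(g, calculator_job(channel, ms,
                                      node_calcs = calcs$node,
                                      rel_calcs = calcs$rel, mu = mu))
}
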