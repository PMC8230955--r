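# Closed-form graph sizing: node/edge count predictions for epoched signal
# networks, a fixed-record disk model, and verification against a built graph.
#
# A signal of rate f Hz and duration t s epoched at te s yields
# s = floor(t / te) SignalValue nodes per measure (equivalently
# floor(f t / te_samples) with the epoch length expressed in samples,
# te_samples = f te, keeping the units consistent with the sliding-window
# formula below); with m measures, S = m s nodes in total. Sliding windows
# of w samples with o samples overlap yield s = floor((f t - w) / (w - o)).
# Relationship calculators connect every same-epoch pair of measures, so a
# complete graph of r = m (m - 1) / 2 edges arises per epoch and
# R = s r in total.

#' Sizing parameters
#'
#' @param f Sampling rate in Hz.
#' @param t Signal duration in seconds.
#' @param m Number of measures (time series).
#' @param te Epoch length in seconds (fixed mode).
#' @param w,o Window and overlap lengths in samples (sliding mode).
#' @return A `sizing_params` list. Exactly one of `te` or `(w, o)` must be
#'   given, with `o < w`.
#' @export
sizing_params <- function(f, t, m, te = NULL, w = NULL, o = NULL) {
  if (is.null(te) == (is.null(w) || is.null(o)))
    pg_abort("give exactly one of te or (w, o)", "pg_invalid_params")
  if (!is.null(w) && (o >= w || o < 0))
    pg_abort("sliding mode requires 0 <= o < w", "pg_invalid_params")
  if (f <= 0 || t <= 0 || m < 1)
    pg_abort("f, t must be positive and m >= 1", "pg_invalid_params")
  structure(list(f = f, t = t, m = m, te = te, w = w, o = o),
            class = "sizing_params")
}

#' Predict SignalValue node and INFLUENCE_ON edge counts
#'
#' @param params A [sizing_params()] object.
#' @return A `sizing_report`: `s` (nodes per measure), `S` (total signal
#'   nodes), `r` (edges per epoch), `R` (total edges, with no threshold).
#' @export
predict_counts <- function(params) {
  stopifnot(inherits(params, "sizing_params"))
  n <- floor(params$f * params$t + 1e-9)
  s <- if (!is.null(params$te)) {
    spp <- params$f * params$te  # epoch length in samples
    floor(n / spp + 1e-12)
  } else {
    max(0, floor((n - params$w) / (params$w - params$o)))
  }
  r <- params$m * (params$m - 1) / 2
  structure(list(s = s, S = params$m * s, r = r, R = s * r),
            class = "sizing_report")
}

#' @export
print.sizing_report <- function(x, ...) {
  cat(sprintf("<sizing_report> s = %g nodes/measure, S = %g signal nodes, r = %g edges/epoch, R = %g edges\n",
              x$s, x$S, x$r, x$R))
  if (!is.null(x$disk_bytes))
    cat(sprintf("  estimated disk: %g B\n", x$disk_bytes))
  invisible(x)
}

#' Estimate disk usage from fixed record sizes
#'
#' Uses the fixed record lengths of a Neo4j-style store: 15 B per node,
#' 34 B per relationship, 41 B per property record, plus 128 B per
#' string-valued and 128 B per array-valued property value record (additive
#' with the 41 B property record).
#'
#' @param x A `property_graph` (counted directly) or a list with `nodes`,
#'   `relationships`, `properties`, `string_props`, `array_props` counts.
#' @return Estimated bytes (numeric).
#' @export
estimate_disk <- function(x) {
  if (inherits(x, "property_graph")) {
    nodes <- length(pg_node_ids(x))
    rels <- length(pg_edge_ids(x))
    props <- 0L; strs <- 0L; arrs <- 0L
    count <- function(p) {
      props <<- props + length(p)
      for (v in p) {
        if (length(v) > 1) arrs <<- arrs + 1L
        else if (is.character(v)) strs <<- strs + 1L
      }
    }
    for (id in pg_node_ids(x)) count(pg_node(x, id)$props)
    for (id in pg_edge_ids(x)) count(pg_edge(x, id)$props)
    x <- list(nodes = nodes, relationships = rels, properties = props,
              string_props = strs, array_props = arrs)
  }
  15 * (x$nodes %||% 0) + 34 * (x$relationships %||% 0) +
    41 * (x$properties %||% 0) + 128 * (x$string_props %||% 0) +
    128 * (x$array_props %||% 0)
}

#' Verify predicted counts against a built graph
#'
#' Counts SignalValue nodes and INFLUENCE_ON edges in the graph and compares
#' them with [predict_counts()]. With no relationship threshold the match
#' must be exact; with a threshold the actual edge count can only fall below
#' the prediction.
#'
#' @param g A `property_graph` built from a signal matching `params`.
#' @param params A [sizing_params()] object.
#' @return List with `predicted`, `actual` and logical `match`.
#' @export
verify_counts <- function(g, params) {
  pred <- predict_counts(params)
  actual <- list(
    S = length(g$label_index[["SignalValue"]] %||% integer()),
    R = length(pg_match(g, label = "INFLUENCE_ON", what = "edges"))
  )
  list(predicted = pred, actual = actual,
       match = (pred$S == actual$S) && (pred$R == actual$R))
}
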