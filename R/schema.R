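# Domain layer: typed constructors wiring experiments, participants,
# recordings, channels and measures into the graph schema.
#
# A Recording node represents one participant's participation in one
# experiment: Recording -PART_OF-> Experiment,
# Participant -TAKES_PART_IN-> Recording,
# Recording -HAS_RECORDING_TYPE-> Channel (one per recorded channel; a
# Channel node is per-recording, not a channel in general), and
# Channel -HAS_MEASURE-> Measure for every declared signal.

#' Create an Experiment node
#'
#' @param g A `property_graph`.
#' @param name Unique experiment name (uniqueness integrity constraint).
#' @param activity,place Optional descriptive properties.
#' @param extra Named list of additional properties (registered on the fly).
#' @return The Experiment node id.
#' @export
create_experiment <- function(g, name, activity = NULL, place = NULL,
                              extra = list()) {
  if (!is.character(name) || !nzchar(name))
    pg_abort("experiment name must be a non-empty string",
             "pg_invalid_property")
  pg_register_property(g, names(extra))
  pg_create_node(g, "Experiment",
                 c(list(name = name, activity = activity, place = place),
                   extra))
}

#' Create a Participant node
#'
#' @param g A `property_graph`.
#' @param user_id Unique non-negative integer identifier.
#' @param gender,age Optional descriptive properties.
#' @param extra Named list of additional properties.
#' @return The Participant node id.
#' @export
create_participant <- function(g, user_id, gender = NULL, age = NULL,
                               extra = list()) {
  if (!is.numeric(user_id) || user_id < 0)
    pg_abort("user_id must be a non-negative integer", "pg_invalid_property")
  pg_register_property(g, names(extra))
  pg_create_node(g, "Participant",
                 c(list(user_id = user_id, gender = gender, age = age),
                   extra))
}

#' Declare a channel
#'
#' @param type Channel type, e.g. `"EEG"`, `"ECG"`, `"GSR"` or
#'   `"Annotation"` (mandatory; integrity constraint on `Channel.type`).
#' @param recording_standard Optional, e.g. `"10-20"` for EEG.
#' @param extra Named list of additional properties.
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(type, recording_standard = NULL, extra = list()) {
  if (is.null(type) || !nzchar(type))
    pg_abort("channel type is mandatory", "pg_constraint_violation")
  structure(list(type = type, recording_standard = recording_standard,
                 extra = extra), class = "channel_spec")
}

#' Declare a measure
#'
#' A timestamp measure binds values to single time moments, an epoch measure
#' to intervals, and an electrode measure is the special epoch measure that
#' distinguishes same-type signals by body placement (its `name` is the
#' electrode label, e.g. a 10-20 position or `left`/`right`/`GSR`).
#'
#' @param signal_id Unique integer signal identifier (uniqueness constraint
#'   on `Measure.signal_id`).
#' @param kind `"timestamp"`, `"epoch"` or `"electrode"`.
#' @param name Measure name; for electrode measures, the electrode label.
#' @param datatype,range Required for non-electrode measures. `range` is a
#'   string of the form `"low..high inclusive"`; [parse_range()] recovers the
#'   numeric bounds.
#' @param fs Optional sampling rate in Hz, stored on the Measure node.
#' @return A `measure_spec` list.
#' @export
measure_spec <- function(signal_id, kind = c("timestamp", "epoch", "electrode"),
                         name, datatype = NULL, range = NULL, fs = NULL) {
  kind <- match.arg(kind)
  if (kind != "electrode" && (is.null(datatype) || is.null(range)))
    pg_abort("timestamp/epoch measures need datatype and range",
             "pg_invalid_property")
  structure(list(signal_id = signal_id, kind = kind, name = name,
                 datatype = datatype, range = range, fs = fs),
            class = "measure_spec")
}

#' Parse a measure range string
#'
#' @param range A string like `"1..9 inclusive"`.
#' @return Numeric `c(low, high)` or `NULL` if unparseable.
#' @export
parse_range <- function(range) {
  m <- regmatches(range, regexec(
    "^\\s*(-?[0-9.]+)\\s*\\.\\.\\s*(-?[0-9.]+)", range))[[1]]
  if (length(m) < 3) return(NULL)
  c(as.numeric(m[2]), as.numeric(m[3]))
}

#' Create a Recording with its channels
#'
#' @param g A `property_graph`.
#' @param experiment,participant Existing node ids.
#' @param channels Non-empty list of [channel_spec()] objects.
#' @param extra Named list of additional Recording properties (e.g.
#'   `source`, the originating database).
#' @return A `recording_handle`: list with `recording`, `experiment`,
#'   `participant` and `channels` node ids.
#' @export
create_recording <- function(g, experiment, participant, channels,
                             extra = list()) {
  pg_node(g, experiment); pg_node(g, participant)
  if (length(channels) == 0)
    pg_abort("a recording needs at least one channel", "pg_invalid_property")
  pg_register_property(g, names(extra))
  rec <- pg_create_node(g, "Recording", extra)
  pg_create_edge(g, rec, experiment, "PART_OF")
  pg_create_edge(g, participant, rec, "TAKES_PART_IN")
  ch_ids <- vapply(channels, function(cs) {
    if (!inherits(cs, "channel_spec")) cs <- do.call(channel_spec, cs)
    pg_register_property(g, names(cs$extra))
    ch <- pg_create_node(g, "Channel",
                         c(list(type = cs$type,
                                recording_standard = cs$recording_standard),
                           cs$extra))
    pg_create_edge(g, rec, ch, "HAS_RECORDING_TYPE")
    ch
  }, integer(1))
  structure(list(recording = rec, experiment = experiment,
                 participant = participant, channels = ch_ids),
            class = "recording_handle")
}

#' Attach measure nodes to a channel
#'
#' Creates one Measure node per spec, labelled `Measure` plus
#' `TimestampMeasure`/`EpochMeasure`/`ElectrodeMeasure` by kind, each wired
#' with a HAS_MEASURE edge from the channel.
#'
#' @param g A `property_graph`.
#' @param channel Channel node id.
#' @param specs List of [measure_spec()] objects with distinct signal ids.
#' @return Integer vector of Measure node ids.
#' @export
attach_measures <- function(g, channel, specs) {
  pg_node(g, channel)
  sids <- vapply(specs, function(s) as.numeric(s$signal_id), numeric(1))
  if (anyDuplicated(sids))
    pg_abort("duplicate signal_id within one attach_measures call",
             "pg_constraint_violation")
  vapply(specs, function(s) {
    if (!inherits(s, "measure_spec")) s <- do.call(measure_spec, s)
    lab <- switch(s$kind, timestamp = "TimestampMeasure",
                  epoch = "EpochMeasure", electrode = "ElectrodeMeasure")
    m <- pg_create_node(g, c("Measure", lab),
                        list(signal_id = s$signal_id, name = s$name,
                             datatype = s$datatype, range = s$range,
                             fs = s$fs))
    pg_create_edge(g, channel, m, "HAS_MEASURE")
    m
  }, integer(1))
}

channel_measures <- function(g, channel, kind = NULL) {
  ms <- out_neighbors(g, channel, "HAS_MEASURE")
  if (is.null(kind)) return(ms)
  ms[vapply(ms, function(m) measure_kind(g, m) == kind, logical(1))]
}

#' @export
print.recording_handle <- function(x, ...) {
  cat(sprintf("<recording_handle> recording %d, experiment %d, participant %d, %d channels\n",
              x$recording, x$experiment, x$participant, length(x$channels)))
  invisible(x)
}
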