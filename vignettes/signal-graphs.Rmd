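---
title: "Storing and querying multimodal physiological signals as a labeled property graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing and querying multimodal physiological signals as a labeled property graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiograph)
```

## The data model

Affective-computing experiments produce heterogeneous series — EEG, ECG and
skin conductance at different sampling rates, emotion annotations at yet
other rates — plus the context that makes them interpretable: who was
recorded, in which experiment, through which channel. `physiograph` stores
all of it in one labeled property graph, the tuple
$(V, E, \rho, \lambda_1, \lambda_2, \sigma)$: a finite node set $V$, an edge
set $E$ disjoint from it, a total map $\rho$ giving every edge an ordered
node pair (edges are directed), a total map $\lambda_1$ assigning each node
a non-empty set of labels, a total map $\lambda_2$ assigning each edge
exactly one label, and a partial property map $\sigma$ over
$(V \cup E) \times \mathrm{Prop}$ in which each element carries at most one
value per property (scalar or homogeneous list). Missing values are
expressed by property absence, never by sentinels.

The schema layers domain meaning on top: an `Experiment` node anchors each
study; a `Recording` node (one per participant-in-experiment) points at it
via `PART_OF`, is pointed at by its `Participant` via `TAKES_PART_IN`, and
owns per-recording `Channel` nodes via `HAS_RECORDING_TYPE`. Channels carry
`Measure` nodes (`HAS_MEASURE`) of three kinds. A *timestamp measure* binds
each value to a single moment (`IN_SEC`); an *epoch measure* binds each
value to an interval (`START_IN_SEC` / `END_IN_SEC`); an *electrode
measure* is the special epoch measure that distinguishes same-type signals
by body placement (10-20 scalp positions for EEG, `left`/`right` for ECG, a
single `GSR` electrode). Signal values form a linked list of `SignalValue`
nodes chained by `NEXT`, with the measure's `HAS_SIGNAL` edge marking the
head. Annotation streams (valence/arousal or categorical emotion scores)
are ordinary timestamp or epoch measures on a channel of type
`"Annotation"` — they need no special node type.

Time is a shared resource: `Timestamp` nodes hold integer millisecond
offsets from the start of the recording and form a single `NEXT`-linked
chain, spliced on demand by get-or-create. Sub-millisecond times are
rejected rather than rounded. Because the uniqueness constraint on
`Timestamp.value` is graph-wide, every experiment stored in one graph
shares the chain; each `Experiment`'s `TAKES` edge tracks the current
earliest node. Signals at different rates or epoch lengths therefore join
naturally on shared boundary timestamps.

Integrity constraints are transactional: every mutation is validated first
and rejected whole on violation. Four uniqueness constraints
(`Experiment.name`, `Participant.user_id`, `Timestamp.value`,
`Measure.signal_id`) and one mandatory-property constraint (`Channel.type`)
are registered by default; `pg_register_constraint()` adds more, refusing
registration if existing contents already violate it.

## Epoching and its bookkeeping

A raw signal with rate $f$ Hz and duration $t$ s epoched at $t_e$ s yields

$$s = \left\lfloor \frac{t}{t_e} \right\rfloor$$

full epochs per measure (trailing partial samples are discarded), hence
$S = m\,s$ `SignalValue` nodes for $m$ measures. The sliding-window variant
with window $w$ and overlap $o$, both in samples, yields

$$s = \left\lfloor \frac{f t - w}{w - o} \right\rfloor$$

windows; `epochize()` emits exactly the first $s$ windows so that
construction and the closed form agree to the integer (the one further
window that plain enumeration could cut is deliberately discarded). Note
both formulas count samples per epoch: the fixed-epoch count is
$\lfloor f t / (f t_e) \rfloor$ with the epoch length expressed in samples,
which keeps the two modes dimensionally consistent. Relationship
calculators connect every same-epoch pair of measures — a Cartesian rather
than strong graph product, so no edges cross epochs — giving

$$r = \frac{m(m-1)}{2}, \qquad R = s\,r$$

`INFLUENCE_ON` edges when no threshold is set. `predict_counts()` evaluates
these forms and `verify_counts()` checks them against a built graph; the
test suite requires exact integer agreement over randomized parameter
grids (50 fixed-epoch and 20 sliding-window draws with $f \le 16$ Hz,
$t \le 30$ s, $m \le 4$ — small enough to build in seconds, large enough to
exercise every floor-boundary case).

Epoch intervals are half-open $[\mathrm{start}, \mathrm{end})$ so that
consecutive epochs share their boundary timestamp node without
double-counting. Fixed epochs must be a whole number of milliseconds;
sliding-window starts that fall between milliseconds are rounded to the ms
grid (the timeline itself stays integer-valued, and starts are verified to
remain strictly increasing). The non-overlap requirement is relaxed to
"starts strictly increasing" in sliding mode only.

`estimate_disk()` prices a graph with fixed record lengths: 15 B per node,
34 B per relationship, 41 B per property record, plus 128 B for each
string-valued and each array-valued property value. The 41 B property
record is charged additively under the 128 B value records, and
calculator-written properties count like any other; a list-valued `data`
array counts once as one array record.

## Preprocessing

Band-limiting uses a linear-phase windowed-sinc FIR (default up to 513
taps, adapted down for short signals) applied forward and backward, so the
output is zero-phase. An FIR was chosen over an IIR design because the
default band edges (0.5 Hz against a 64-128 Hz Nyquist) put IIR
transfer-function coefficients in numerically fragile territory at the
orders needed for comparable stop-band attenuation, while the FIR is
unconditionally stable and its attenuation is known in closed form (the
tests check a 50 Hz tone against the filter's own analytic response).
Signals are mean-centered before filtering to avoid start/end transients
from the DC offset; a pure low-pass restores the level afterwards.

Channel defaults: EEG band-pass 0.5-45 Hz; ECG band-pass 0.5-40 Hz; skin
conductance *unfiltered*. The last is deliberate: the SCR peak detector
smooths internally, and a zero-phase low-pass is acausal — it spreads a
response onset backwards in time, so a bump just after an epoch boundary
becomes visible as a rise inside the previous epoch and corrupts per-epoch
peak counts. All settings, including resampling (off by default), are
per-import configurable.

## Calculators

Calculators are pluggable: a *node calculator* maps one epoch's sample
array to a named property list written onto the `SignalValue` node; a
*relationship calculator* maps two same-epoch arrays to a scalar stored on
an `INFLUENCE_ON` edge, created only when the value reaches the optional
threshold $\mu$ (always created when $\mu$ is unset). Edges run from the
lexicographically smaller electrode name to the larger — the statistic is
symmetric, so the direction is arbitrary but must be deterministic.

**EEG band power.** The power spectral density is estimated with Thomson's
multitaper method: time-bandwidth product $NW = 4$, $K = 2 \cdot 4 - 1 = 7$
Slepian tapers, combined by an eigenvalue-weighted average
$\hat S = \sum_k \lambda_k \hat S_k / \sum_k \lambda_k$ that compensates
the energy loss of higher-order tapers. The tapers come from the standard
symmetric tridiagonal eigenproblem, solved densely up to length 512 and
spline-interpolated (then renormalized) for longer epochs — the
concentrations $\lambda_k$ are re-evaluated on the final tapers by
integrating the squared spectrum over the concentration band, and for the
default 20 s epochs the interpolated tapers stay orthonormal to within a
few percent, which is immaterial after the eigenvalue weighting. Band
power integrates the PSD over delta $[0.5, 4)$, theta $[4, 8)$, alpha
$[8, 12)$, beta $[12, 30)$ and gamma $[30, 100)$ Hz; half-open intervals
resolve the shared printed boundaries, and bands are clipped at Nyquist.

**ECG.** R-peaks are found on a differentiated (16 ms span), squared and
48 ms-smoothed detection signal under a threshold set at half the signal's
99.5th percentile, with a 200 ms refractory period; each detection is
refined to the raw-signal maximum within 40 ms. IBI is the series of
successive R-R intervals in ms. HRV is defined here as the successive
differences of the IBI series — the statistic is not pinned down further
upstream, so this choice (close in spirit to RMSSD-style short-term
variability) is exposed through the calculator registry rather than
hard-coded into the schema. Each series is summarized per epoch by min,
max, variance and mean: eight values per electrode. Fewer than three
detected beats yields all-`NA` features, not an error.

**Skin conductance.** The epoch is smoothed with a 0.25 s moving average;
onsets are upward zero-crossings of the derivative; a peak is counted when
the onset-to-maximum rise reaches the amplitude threshold (default 0.01
signal units). `GSR_min`, `GSR_max`, `GSR_avg` summarize detected peak
amplitudes and `no_of_peaks` counts them. The detector is validated
against generator ground truth (injected SCR counts recovered exactly at
the default injection amplitude), not against any particular published
parameterization.

**Mutual information.** Both series are discretized with equal-width bins
over their observed ranges — $\lceil \sqrt n \rceil$ bins capped at 16 by
default — and the plug-in (maximum-likelihood) entropies of the joint
histogram give $I(X;Y) = H(Y) - H(Y\mid X)$ in bits (base 2; the base is a
convention, exposed only through the returned entropies). The plug-in
estimate is non-negative up to floating-point noise, which is clamped at
$-10^{-12}$. Symmetry is exact by construction since the implementation
evaluates $H(X) + H(Y) - H(X,Y)$.

## Retrieval

Five canonical queries cover the intended access patterns: experiments
holding a given measure under a given channel type; the measures
themselves; the time series of one signal (timestamp signals report `NA`
epoch ends); the multivariate series of several signals; and the same
restricted by per-signal predicates. Multivariate rows anchor on the first
signal and left-join the others on the shared *start* timestamp node, so a
signal with no value at an anchor time contributes `NA`; a restriction on
a missing value drops the row (`NA` fails every predicate, mirroring
`WHERE` semantics). `export_signal_table()` flattens a channel type into
$n$ requested value columns plus seven metadata columns (experiment,
source database, participant, channel type, measure name, epoch start and
end). `extract_feature_vectors()` assembles per-epoch vectors in a fixed
order — five band powers per EEG electrode, eight HRV/IBI statistics per
ECG electrode, four skin-conductance values, then pairwise `mi` values in
lexicographic electrode order — so the standard 14-EEG / 2-ECG / 1-GSR
montage yields $5 \cdot 14 + 8 \cdot 2 + 4 = 90$ node-level and
$\binom{14}{2} = 91$ edge-level features, 181 in total, with
valence/arousal labels and their affect quadrant (HVHA/HVLA/LVHA/LVLA from
the value signs) appended when an annotation channel is present. The
electrode order defaults to lexicographic and is configurable; it is
recorded in the column names.

Every native query is checked against independent oracles: relational
joins over a raw edge-table scan for the search queries, and
construction-time ground truth for the series queries, across randomized
small graphs. The equivalent openCypher text for each pattern, and `CREATE`
scripts plus constraint DDL for whole graphs, are emitted as byte-stable
text; the replay parser accepts exactly the emitted dialect (there is no
general openCypher executor here) and rebuilds through the ordinary
creation operations, so constraints are re-enforced during replay.

## The synthetic-data generator

`gen_session()` produces a complete on-disk session — one CSV per measure
plus a YAML manifest — as a deterministic function of its seed. Defaults
describe the standard study condition used throughout the tests: 120 s,
14-electrode EEG at 128 Hz (sinusoids at the five band-center frequencies
2, 6, 10, 20, 40 Hz, unit-variance noise, and a common component shared by
all electrodes so pairs carry nonzero mutual information), left/right ECG
at 256 Hz with R-R intervals drawn from $N(1000, 50^2)$ ms truncated at
300 ms, one skin-conductance electrode at 32 Hz with amplitude-0.5 SCR
bumps (difference-of-exponentials kernel, 0.75 s rise, 2 s decay) every
15 s over a constant tonic level, and per-epoch valence/arousal drawn
uniformly from $[-1, 1]$. Annotation streams can instead be emitted as
timestamp signals at 1, 20 or 25 Hz from the same piecewise-constant
truth, in which case epoch-averaging recovers identical values regardless
of rate.

What the generator does *not* emulate bounds what the passing tests can
show: spectra are line-plus-white rather than $1/f$; there are no
artifacts, electrode pops, baseline drift or movement; the ECG template
has no P or T waves; SCRs never overlap. Detector performance on these
signals demonstrates correct implementation of the documented procedures
and exact recovery under the stated conditions — not clinical-grade
performance on recorded data.

## Numerical choices and problem sizes

Test and validation sizes are chosen to exercise every code path while
keeping the whole suite fast: the sizing grids draw 50 fixed and 20
sliding parameter sets at $f \le 16$ Hz; the permutation null for mutual
information uses $n = 2000$ samples and 1000 shuffles (the independence
property being checked does not depend on $n$); detector recovery runs 100
seeded 20 s ECG epochs. The multitaper/periodogram cross-checks allow 15%
on broadband totals (a genuine method difference, not an error bound) and
25% on white-noise band proportionality. Serialization equality is
checked at nine significant digits, tolerating the last-ulp noise textual
round-trips of doubles can introduce.

## Known limitations

Single-writer, in-memory, no transactions spanning multiple operations.
No EDF/BDF readers, artifact rejection, ICA or channel interpolation. Only
the fixed query patterns run natively; arbitrary openCypher does not.
Inter-epoch and cross-channel influence edges (the strong-product variant)
are out of scope, as are classifier training and normalization pipelines
downstream of feature extraction. The disk model prices record counts
only; it ignores store overhead, indexes and compression.
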