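---
title: "Spike-train features, synchrony and network communities for MEA dose-response studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-train features, synchrony and network communities for MEA dose-response studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meanet)
```

## Scope and data model

`meanet` analyses well-level MEA recordings of cultured neuronal networks
in repeated-measures exposure designs: each well is recorded before dosing
(baseline) and at several later timepoints, and every outcome is expressed
relative to that same well's baseline because absolute activity varies
strongly from well to well.

The data model is deliberately small. A `spike_train` is a strictly
increasing vector of spike times in seconds on the half-open window
`[0, duration)`; a `mea_recording` bundles the trains of one well and one
session with its metadata (device, well, dose condition, timepoint,
duration). Files round-trip exactly through two dialects: an HDF5 layout
(`/spikes/e<k>` float64 datasets plus root attributes, handled by a bundled
h5py helper) and a CSV spike list with a JSON sidecar. Spike times are
never rounded; the JSON bridge and the CSV writer both serialise at 17
significant digits, which is lossless for float64.

## Spike detection and the activity filter

When raw voltage traces are supplied, spikes are detected by amplitude
threshold at 6.5 times the baseline noise SD per electrode. Two details are
choices of this package, because threshold detection is usually done
upstream and descriptions rarely pin them down:

* the noise SD is estimated robustly as `median(|x|)/0.6745`, so the
  spikes themselves do not inflate the threshold;
* detections default to the negative polarity (extracellular action
  potentials are negative-going on planar MEAs) and are separated by a
  1 ms dead time, preventing a multi-sample excursion from counting twice.

Electrodes with fewer than 10 spikes in a session are silent and removed
before any further analysis. The filter is idempotent and monotone in its
threshold, and it never mutates its input.

## Burst detection

Bursts are classified by the max-interval method with the standard
parameter set (`burst_params()`): maximum beginning ISI 0.1 s, maximum end
ISI 0.2 s, minimum interburst interval (IBI) 0.5 s, minimum duration
0.05 s, minimum 6 spikes. The procedure is four ordered steps: open a
candidate where an ISI is at most the beginning threshold; extend while
ISIs stay within the end threshold; merge candidates whose gap is strictly
below the minimum IBI; then discard candidates failing the size or
duration minima.

Two conventions are worth stating because parameter lists do not determine
them:

* **merging precedes filtering**, so two sub-threshold candidates less
  than one IBI apart can combine into one valid burst — the behaviour
  that matches the method's usual implementations;
* boundary comparisons are inclusive for the ISI thresholds and the
  retention minima, and strict for the merge gap. Burst duration is
  measured first spike to last spike, unpadded.

The detector is verified against a literal step-by-step reference
implementation on a thousand randomised trains (identical index spans),
and the burst count is checked to be monotone in the retention thresholds.

## Feature panel and well-level summaries

Per electrode: spike count, firing rate, mean ISI, % of spikes inside
bursts, burst count, bursts per minute, mean burst duration, mean IBI.
Quantities that need at least two events are `NA` when undefined, and `NA`
propagates through summaries by pairwise exclusion — an electrode with no
bursts contributes nothing to burst-duration averages rather than a
spurious zero.

Well-level summaries are weighted means and population-form weighted SDs
over active electrodes. The default weights are event counts — spike
counts for spike features, burst counts for burst features — so that
sparsely firing electrodes do not dominate interval statistics; uniform
weighting is available (`weighting = "uniform"`). Fold change divides a
timepoint's weighted mean by the same well's baseline weighted mean; when
several pre-dose sessions exist their electrode tables are pooled before
summarising. A zero or undefined baseline yields `NA` with a warning,
never infinity. Baseline rows are 1 by construction.

## Synchrony: SPIKE-distance with surrogate normalisation

Pairwise synchrony is built on the SPIKE-distance, a time-scale-adaptive
dissimilarity in `[0, 1]`. At every time `t`, each train `n` contributes

`S_n(t) = (Δt_P x_F + Δt_F x_P) / x_ISI`,

interpolating between the distances of the previous (`t_P`) and following
(`t_F`) spikes to the nearest spike of the other train; the pair profile is

`S(t) = (S_1 x_ISI2 + S_2 x_ISI1) / (2 ⟨x_ISI⟩²)`

and the distance is the time average of `S(t)`. Auxiliary spikes at the
window edges provide the usual edge correction.

**Numerical choice.** The profile is integrated by a midpoint Riemann sum
on a uniform grid (`grid_dt`, default 1 ms; the window is divided into
`round(T/grid_dt)` equal cells), implemented in C++. A uniform grid is
trivially verifiable by refinement — the suite checks both a 10× finer
grid and an independently coded dense-grid R reference, with agreement
well below the statistical scale of any quantity computed from the
distance (tolerance 1e-3). Identical trains give exactly zero regardless
of the grid because every spike-distance term vanishes.

Raw synchrony is `1 − D`. Because the SPIKE-distance has a documented
tendency to score denser spike trains as more similar, the pipeline
normalises against chance: for each electrode pair it simulates
`n_surrogates = 20` pairs of homogeneous Poisson trains with the same
duration and the same two spike counts, and reports

`clip(1 − D_obs / D_rand, 0, 1)`,

with `D_rand` the mean surrogate distance. Identical trains still score
exactly 1 (the numerator is zero before any surrogate is drawn), and
rate-matched independent trains score ≈ 0 in expectation at any rate —
1 Hz and 20 Hz pairs agree within 0.1. The normalisation form, the
surrogate model and the surrogate count are this package's decisions; the
surrogate draw is seeded per electrode pair from the matrix's master seed,
so a synchrony matrix is reproducible and independent of electrode order.
The degenerate case `D_rand = 0` (theoretically possible only for
measure-zero configurations) returns `NA` with a warning.

Synchrony is computed over the full recording; no windowing is applied.

## Network communities

The synchrony matrix defines a complete weighted graph over active
electrodes. Louvain modularity maximisation (two greedy phases, node order
seeded) partitions it; no threshold is applied before community detection
— the 0.7 strong-link cutoff is a display classification only, with ties
at the threshold weak because the convention is strictly "greater than".
The modularity reported with a partition is re-evaluated with the
package's own weighted-modularity formula, which the tests compare against
igraph's value and against exhaustive search over all partitions of small
(≤ 8 node) graphs.

Pooled link distributions are summarised by a normalised histogram over
`[0, 1]`, the pooled mean, and the peaks of a Gaussian kernel density
(Silverman bandwidth) — a peak is reported when its prominence over the
valleys separating it from its neighbours reaches 10% of the maximum
density. "Bimodal" operationally means at least two such peaks.

## The synthetic study generator

The generator exists so the pipeline's behaviour can be validated against
planted ground truth; it is phenomenological, not biophysical. A well is a
set of electrodes partitioned into communities (default two). Each
community experiences network-burst events at `burst_event_rate`
(15/min by default); a fixed fraction `event_sharing` (0.6) of events is
culture-wide — shared times and burst sizes across communities — and the
rest are community-private. Every participating electrode (probability
0.98 per event) emits the event's burst (6–15 spikes, drawn per event;
30 ms intra-burst ISIs) at the event time plus its community's lag
(SD 50 ms) plus its own Gaussian jitter: 2 ms for "tight" electrodes,
10 ms for "loose" ones (half of each community each). A sparse independent
Poisson background (0.005 Hz) is superposed. Dose effects are plain
multipliers on the event and background rates: the default schedule holds
untreated wells at 1, dips the low dose to 0.8 within the first hour with
recovery from 24 h, and suppresses the high dose to 0.2 at all post-dose
timepoints. Per-well ±10% rate wobble (constant across a well's sessions)
reproduces the well-to-well baseline variability that motivates fold-change
normalisation; it cancels exactly in the fold change, which is what makes
multiplier recovery a clean end-to-end check.

Three structural decisions deserve their rationale:

* **Event overlap, not millisecond jitter, separates the synchrony
  modes.** The SPIKE-distance adapts to the local interspike timescale, so
  a few tens of milliseconds of burst-onset jitter are nearly invisible
  next to multi-second inter-burst intervals; what a pair's synchrony
  measures at these timescales is essentially which burst events the two
  electrodes share. The generator therefore plants the bimodal link
  structure of mature cultures through community event overlap:
  within-community pairs share (almost) all events and form the high mode
  near 0.9, cross-community pairs share only the culture-wide fraction and
  form the low mode around 0.3–0.5. Jitter classes remain as realistic
  timing variability and fine-grained ordering within the high mode.
* **The shared fraction of events is deterministic** (`round` of the
  event count) rather than an independent Poisson split. With a Poisson
  split the realized sharing fraction of a 4-minute recording varies
  enough (SD ≈ 0.06) to move the low synchrony mode by ±0.1 between runs;
  fixing the fraction keeps the planted structure where it was put.
* **Burst size is an event property.** If electrodes drew sizes
  independently, the unmatched burst tails would act like private
  activity and cap within-community synchrony well below the observed
  high mode.

The defaults were calibrated once, when the generator was designed, to
produce a mature-culture phenotype — ≈ 2.6 Hz per electrode
(`expected_rate()` gives the closed form), nearly all spikes in bursts,
and pooled baseline link synchrony with density peaks near 0.4 and 0.9 —
and are not adjusted thereafter. The generator does **not** emulate:
bursting-rate adaptation or oscillations, electrode-specific amplitudes
and noise (all electrodes are statistically identical up to class and
community), development or drift between sessions beyond the dose
multipliers, receptor pharmacology (dose effects are multipliers, not
mechanism), or glia (the cell-type composition of a culture is metadata
only). Passing the pipeline's recovery checks on these simulations
therefore demonstrates correctness of the analysis, not validity of any
biological model.

## Problem sizes used by the stochastic checks

Checks involving simulation use sizes chosen to make their statistical
tolerances comfortable: multiplier recovery runs the full default study
(3 conditions × 6 wells × 7 timepoints) at the design's 1800 s sessions,
where the 6-well mean spike-count fold change estimates each planted
multiplier to a few percent; the bimodality check pools the six untreated
baseline wells at 240 s using a stratified 12-electrode subset per well
(the full 59-electrode matrix is ~25× more pairwise work and adds nothing
to the distributional picture); the SPIKE-distance oracle uses 100 random
60 s Poisson pairs; community recovery uses 50 seeded planted matrices.

## Known limitations

* The surrogate normalisation rests on spike-count-matched homogeneous
  Poisson surrogates; structured null hypotheses (e.g. rate-modulated or
  bursty surrogates) would give different normalised values.
* Louvain is a greedy heuristic: on weakly separated structure, different
  seeds can return different partitions; only small graphs can be checked
  against the exhaustive optimum.
* Burst detection uses one fixed parameter set; adaptive detectors and
  multi-electrode network-burst detection are out of scope.
* The HDF5 reader handles the package's own layout, not vendor formats;
  band-pass filtering of raw traces is assumed done upstream.
* Group statistics (ANOVA and post-hoc tests across conditions) are out of
  scope by design: the pipeline emits tidy tables for external tools.
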