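---
title: "Models and conventions for halting-circuit analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions for halting-circuit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyhalt)
```

# Scope

A walking insect can stop in more than one way: descending "halt" neurons
in the brain can inhibit walking-promoting descending neurons (a *walk-OFF*
mechanism), or circuits in the ventral nerve cord can lock stance-phase leg
joints (a *brake* mechanism). Dissecting these mechanisms takes four kinds
of quantitative machinery, and this package implements all of them against
a common set of conventions: a connectome-constrained spiking network
simulator, a 3D gait-kinematics pipeline for tethered walking on a
spherical treadmill, free-walking arena quantification, and calcium-trace
analysis. A fifth module generates synthetic versions of all four input
classes with planted ground truth, which is how the test suite validates
every stage end to end.

# The spiking network model

## Connectivity and signs

The simulator consumes two columnar tables of the kind exported by
whole-brain connectome resources: a neuron table
(`id,label,hemisphere,nt,class_tag`) and an edge table (`pre,post,count`).
Connection strength is proportional to the synapse count:
`w = sign × count × w_unit` millivolts per presynaptic spike. The sign is
determined by the presynaptic neurotransmitter prediction — GABA and
glutamate are inhibitory, everything else (acetylcholine, dopamine,
serotonin, octopamine, and unknown) excitatory. Unknown transmitters
default to excitatory with a warning. This makes the graph Dale-consistent
by construction. Duplicate `(pre, post)` rows are summed, since dumps often
split one connection across neuropils; autapses are kept as ordinary edges
(faithfulness to the dump). Hemisphere is metadata only — no automatic
mirror pairing is attempted, because hemisphere selection in circuit
figures is a manual, question-driven choice.

## Dynamics and integration

Each neuron is a leaky integrate-and-fire unit with resting potential
`v_rest`, threshold `v_thresh`, reset `v_reset`, membrane time constant
`tau_mem` and absolute refractory period `t_refract`. The network has no
intrinsic drive: with no stimulation, nothing ever spikes, which the test
suite asserts for arbitrary connectomes. Numeric constants are not
re-derived here; the defaults in `lif_params()` are the published constants
of the whole-brain fly LIF model of Shiu et al. (2024) — rest −52 mV,
threshold −45 mV, reset −52 mV, τ_m 20 ms, refractory 2.2 ms, delay 1.8 ms,
w_unit 0.275 mV/synapse — and every one is a plain argument, defined in
exactly one place.

Integration is forward Euler at `dt = 0.05` ms. The update order per step
is part of the engine's contract, because the test suite holds the engine
to *bit-exact* agreement with an independent scalar reference integrator:

1. membrane update (refractory neurons stay clamped at reset and count
   down);
2. synaptic delivery — recurrent events whose delay expires this step,
   then external input events stamped with this step, both applied after
   the membrane update;
3. threshold test, spike recording (at the end of the step), reset, and
   queueing of outgoing weights `delay` later (delays round to the nearest
   step).

Two synaptic kernels are available: `delta` (each spike deposits its whole
weight at arrival; the default, and the one checked against the reference
integrator) and `exp` (the same charge low-pass filtered with `tau_syn`).
Inputs arriving during the refractory period are discarded in delta mode;
in exponential mode the synaptic trace accumulates regardless, since it
models a conductance that outlives the refractory clamp.

## Stimulation, silencing, and randomness

Stimulation adds an independent homogeneous Poisson train to each target
(`stim_epoch()`), discretized to the integration grid (one Bernoulli draw
per step, which keeps the empirical rate unbiased). Each input spike
depolarizes its target by `strength × w_unit`; the default strength of 25
synapse-equivalents makes a 150 Hz drive produce sustained firing near the
input rate under the default constants, matching how optogenetic drive is
mimicked in connectome models. Silencing severs all outgoing connections of
the chosen neurons *before* integration; they still integrate and may
spike. The test suite verifies that protocol-level silencing is bit-identical
to structurally deleting those edges first.

The standard protocol is 30 trials of 1,000 ms. Every `(trial, target,
epoch)` triple draws from its own substream derived from the protocol seed
by a fixed integer mix, so adding a readout or an epoch never perturbs
existing streams, and intact/silenced sweep pairs see identical input
spikes — difference maps are therefore free of trial-resampling noise.

## Rates, responders, sweeps, wiring diagrams

`firing_rates()` reports the trial-averaged rate, either scalar over a
window (spikes / trials / window length) or binned and optionally smoothed
with a Gaussian kernel (σ 25 ms is the heat-map convention; smoothing
preserves the time-integral of interior activity to well under 1%).
`top_responders()` ranks by scalar rate, descending, ties broken by
ascending id; the ranking window is the caller's choice because published
heat maps do not pin it down — both the full trial and the co-stimulation
window are reasonable. `rate_sweep()` evaluates a full
simulate-plus-rates run per grid cell over two stimulation-rate axes, with
an optional silenced counterpart and difference grid (silenced − intact).

Wiring diagrams are the thresholded signed graph used in circuit
schematics: nodes above a firing-rate floor (10.3 and 20 Hz are
conventional choices for descending-neuron displays; both are plain
arguments because no derivation for them exists), edges of at least five
synapses among retained nodes, and node values normalized to the maximum
retained rate. Raising either threshold can only shrink the diagram, which
the tests assert as a monotonicity property.

# Gait kinematics on the ball

## Sphere fit

The treadmill ball is not tracked; its position and radius are recovered
from the tarsal tips, which lie on the surface during stance. `fit_ball()`
minimizes the squared orthogonal distance Σ(‖p − c‖ − r)² by Gauss–Newton,
initialized from the one-shot algebraic fit (the linear system in
|p|² = 2p·c + (r² − |c|²)). The fit is deterministic given its
initialization; degenerate (coplanar) clouds are rejected. Tests require
recovery to < 1e−6 mm on noiseless clouds and < 0.05 mm radius error at
0.01 mm isotropic noise across 100 seeds, with the algebraic solver as the
independent oracle.

## Swing/stance classification

A tip within a fractional band of the radius about the surface is stance,
otherwise swing. The conventional band is "0.05% of the radius", read
literally as 5×10⁻⁴ · r. That is a suspiciously tight band for real pose
reconstructions — it may well mean a 0.05 *fraction* — so the band is a
plain scalar argument (`stance_tol_frac`), with the literal reading as the
default. Phases shorter than 10 ms are filtered out; since "filtered out"
underdetermines the rewrite, the rule here is: repeatedly take the shortest
sub-threshold segment and merge it into the *longer* flanking phase (ties
go to the preceding phase), until every segment meets the minimum. Segments
are half-open `[onset, offset)` in 1-based frames — the package follows R's
native indexing throughout.

## Swing-initiation zone

Legs launch swings from a direction-dependent range of femur–tibia flexion
angles. The zone is defined from the empirical swing-onset angles: below
their 25th percentile for forward walking, above their 75th for backward
walking, with at least 20 onset angles required. Percentiles use linear
interpolation between closest ranks (R's type-7 convention), fixed so
thresholds are reproducible. Per trial, `siz_metrics()` counts zone
entries (strict crossings; a trial starting inside the zone counts one
entry at its first frame), dwell times (entry to exit, truncated at the
window end) and the percentage of entries containing a swing onset; trials
with zero entries have an undefined percentage and are excluded from
averages. All of it is validated against a brute-force frame scanner on
100 randomized fixtures.

## Stops, swing durations, grooming

A ball stopping bout is a period with average ball velocity below
0.8 mm s⁻¹ lasting at least 250 ms. "Average" is underdetermined
(instantaneous vs running mean); the default here is a centered 250 ms
running mean, and setting the smoothing window to one sample gives the
instantaneous reading — which is also how the ground-truth recovery tests
run, since smoothing deliberately blurs onsets. Swing-duration statistics
around a stimulation onset: the median of completed pre-onset swings, and
the full duration of the swing in progress at onset (undefined if the
onset lands in stance). Grooming stability is the standard deviation of
the supporting legs' femur–tibia angle per (manually scored) bout — for a
sinusoidal angle of amplitude A this converges to A/√2, which the tests
use as a closed form — plus ball movement, defined as the sum over the
three axes of absolute rotational speed (a signed sum could cancel),
averaged over the bout.

# Arena locomotion

Velocities are finite differences at the tracker frame rate; heading is
unwrapped before differencing; angular velocity is reported as an absolute
value and rotation is the running integral of that absolute angular
velocity. Smoothing is a centered moving average with edge truncation.
Pivots: smoothed (0.5 s) angular velocity above two rotations per second
(720°/s) with translational velocity below 5 mm/s. Stops come in two
published variants: the food-assay rule (smoothed velocity < 2 mm/s for at
least ten frames, robust to tracker jitter during feeding) and the
free-walking rule, whose description ("smoothed translational velocity
(1.5 mm s⁻¹) below a threshold defined previously") does not disambiguate
which number is the threshold and which the smoothing parameter — both are
arguments, defaulting to a 1.5 mm/s threshold with 0.5 s smoothing.

Per-trial metrics integrate path length and rotation over
`[onset, onset + 2 s)`; the 2 s horizon targets the strong early part of
optogenetic walking phenotypes, and metrics on constant-velocity data
scale linearly with it. The sucrose preference index is the standard
two-choice time-based index `(t_sucrose − t_blank)/(t_sucrose + t_blank)`
— the name is conventional, the formula is this package's explicit choice.
Food-zone analysis validates the supplied first-encounter frame against
the geometry (within 3 mm of the blob center), then quantifies stops and
velocities among in-zone frames during the 5 s after the encounter.

# Calcium traces

ΔF/F = (F − F₀)/F₀ under three baseline conventions, selected by `mode`:
the mean of the 2 s before stimulation onset, the 10th percentile of that
window (robust to baseline activity, the muscle-imaging convention), or
the median of the 300 ms before a movement onset. Response comparisons use
the trapezoidal area under ΔF/F over 0–2 s post-stimulation. Ratiometric
traces divide the calcium-sensitive by the calcium-insensitive channel so
common-mode multiplicative artifacts cancel exactly, then express ΔR/R
against the recording-median baseline and z-score over the recording; the
median/whole-recording choices are this package's (a per-bout baseline is
equally defensible and the functions accept pre-sliced input). Pixel-wise
correlation maps are plain Pearson correlations against a behavior
reference, with the reference block-averaged down to the imaging clock
(2–6 Hz imaging vs 50–200 Hz behavior) so no imaging samples are invented;
constant pixels are masked and reported as 0. The lagged cross-correlation
reports Pearson correlation of `activity(t + L)` against `velocity(t)`
over the overlap for lags in ±max_lag, pooling recordings by concatenation
after per-recording mean removal.

# Synthetic data and what passing tests mean

The generators target *structure*, not realism: they realize the sampling
regimes of the real rigs (200 Hz pose, 50 Hz ball tracker, 30 Hz arena,
2–6 Hz imaging, 150 Hz stimulation) and plant exactly the features the
analyses claim to detect. `synth_connectome()` plants named motifs — the
canonical `walkoff_motif_spec()` wires an excitatory walking command and a
GABAergic halt neuron onto one descending neuron with 30 and 40 synapses,
strong enough that the inhibition visibly gates the readout at standard
drive — and the manifest records each motif's expected silencing effect.
`synth_gait()` puts tips on a known sphere during stance and lifts them
mid-frame-aligned during swing (the lift is evaluated at frame midpoints
so that zero-noise phases are recoverable exactly). `synth_track()`
integrates a piecewise behavior plan (walk, stop, pivot, approach), and
`synth_traces()` couples a smoothed positive reference series into a green
channel at a planted lag and gain through an exponential calcium kernel.

Passing round-trips on these fixtures demonstrates that the detectors
recover what they are defined to recover — they do not demonstrate
robustness to pose-estimation failure modes (occlusion, identity swaps),
tracker jitter beyond additive Gaussian noise, slow imaging drift, or
real gait variability. The lag-recovery tests use a near-delta calcium
kernel (τ = 20 ms against a 200 ms imaging sample); with a realistic slow
kernel the peak of the cross-correlation genuinely sits later than the
planted lag, which is a property of the physiology, not a detector error.

# Numerical choices, sizes, limitations

Fixed tolerances and tie-breaks, collected: type-7 percentiles everywhere;
responder ties broken by ascending id; short-phase merge ties to the
preceding phase; delays rounded to the nearest step; spike times recorded
at the end of their step; SIZ dwell truncated at the trial window; masked
zeros for undefined pixel correlations. The engine's trial loop is C++;
everything else is plain R. Test problem sizes are deliberately desk-scale
— motifs of two to five neurons for oracle equivalence (20 seeds), 10–30
trials per simulation, 100-seed property sweeps for the behavioral
scanners — chosen so the whole suite runs in well under a minute while
still exercising every code path; the engine itself handles arbitrary
connectome sizes, but no performance guarantees are made for full-brain
(~10⁵ neuron) runs. Known limitations: no conductance-based or
multi-compartment dynamics, no plasticity, no pose estimation or video
tracking (tables are inputs), no motion correction or ROI segmentation,
and no group-level statistics beyond per-fly metrics — standard tests
(`wilcox.test`, `kruskal.test`) apply directly to the exported tables.
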