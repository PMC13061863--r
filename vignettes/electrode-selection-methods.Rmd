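---
title: "Individualized electrode subsets for P300 BCIs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized electrode subsets for P300 BCIs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A P300-design brain-computer interface (BCI) lets a user answer a
multiple-choice question by attending to one of several pictures whose
labels flash in pseudo-random order. The flash of the attended (target)
label elicits event-related potentials (ERPs) — typically an N200 and a
P300 — that a linear classifier can detect in single-trial EEG. Because
every added electrode costs setup time and hardware, home-use systems run
on a fixed 8-electrode subset of a larger cap. For users whose ERP
topography is spatially typical this default works well; for users with
atypical functional anatomy (for example severe cerebral palsy with early
brain lesions) the informative scalp sites can lie far from the default
positions, and an individualized subset can make the difference between a
usable and an unusable BCI.

`p300select` implements the offline analysis chain for this question:
stimulus-locked epoch handling, SWLDA calibration, greedy forward electrode
selection with a leave-one-trial-out consensus, flash-count tie-breaking,
a per-subject exact binomial improvement test, and a seeded multi-channel
ERP session simulator that stands in for participant EEG.

## Paradigm and containers

A *trial* is one 4-choice question. Each choice's label flashes 10 times
per trial, every label flashing once before any label repeats, so a trial
comprises 40 stimulus-locked epochs of which exactly 10 are targets. Two
acquisition protocols are built in: 600 Hz (50 ms flashes, 116.7 ms
inter-flash interval) and 256 Hz (62.5 ms / 93.75 ms).

An `epoch_set` holds the 4-way array `[trial, flash_event, channel,
sample]` in microvolts over a half-open window (default [0, 1000) ms,
sample 1 at flash onset), the flashed label per event, the correct choice
per trial, a 32-electrode `montage` with schematic planar coordinates, and
the protocol. Session bundles serialize an `epoch_set` as
`metadata.json` plus a long-format full-precision CSV payload that
round-trips bit-exactly.

## Features and SWLDA

Per epoch and channel the pipeline crops to the 0–800 ms response window,
removes the least-squares straight line (which also zeroes the mean), and
decimates to 20 Hz by non-overlapping block means with the integer factor
`round(fs / 20)` (600 Hz: 480 samples, factor 30, 16 bins; 256 Hz: 204
samples, factor 13, 15 bins; a trailing partial block is dropped).
Block-mean decimation was chosen over plain subsampling because it is
anti-aliasing and deterministic; subsampling remains available as a
sensitivity option. Feature columns are channel-major and named
`CH<electrode>_T<bin>`.

SWLDA is realized as stepwise ordinary least-squares regression of the
coded labels (+1 target, −1 non-target) on the feature columns, the
classical construction behind P300 classifier tools: at each iteration the
excluded column with the smallest partial-F p-value enters if p <
`p_enter` (0.10), then included columns with partial-F p > `p_remove`
(0.15) are removed, until a fixed point, the 60-feature cap, or the
iteration safeguard (300) is reached. The implementation works on the
bordered Gram matrix `crossprod(cbind(1, X, y))` with the sweep operator,
which makes each candidate-subset fit independent of the number of epochs
— the property that keeps wrapper-style selection tractable. A candidate
column whose swept pivot falls below `tol` (1e-10, relative) is treated as
collinear and skipped. Within one entry scan all candidates share the same
F degrees of freedom, so the smallest p-value belongs to the largest RSS
reduction and only the arg-max needs an explicit p-value; ties resolve to
the lowest column index. A session in which no feature meets `p_enter`
raises a classed calibration-failure condition, the analogue of a
participant who could not calibrate.

Trials are classified by summing the discriminant scores of the first
`r` flashes of each choice and taking the arg-max (exact ties to the
lowest choice index). When two subsets tie at the full flash count, the
flash count is reduced from 10 and the accuracies are reported at the
first count at which the tie breaks.

## Estimating calibration accuracy

The package deliberately does **not** report resubstitution accuracy.
Stepwise selection with `p_enter = 0.10` over a hundred or more candidate
features overfits its own training epochs so strongly that resubstitution
trial accuracy on pure-noise sessions averages about 0.7 against a chance
level of 0.25 (this is demonstrated in a unit test). Calibration accuracy
is instead estimated by deterministic interleaved k-fold cross-validation
within the calibration trials (default k = 3; trials are dealt to folds by
position): each fold's epochs are scored by the SWLDA model fit on the
remaining folds, and trial classification is evaluated over all trials.
On noise-only sessions this estimate sits at chance, and on real signal it
estimates what the calibration data can support. Resubstitution remains
available (`method = "resubstitution"`) for comparison. The deliverable
model itself is always fit on all calibration trials.

## Greedy forward selection and its ranking criterion

Forward selection starts from an empty chosen set and, at each step,
evaluates `chosen + {candidate}` for every remaining candidate, moving the
arg-max into the chosen set (ties to the earliest montage position) until
M = 8 electrodes are chosen. A candidate whose fit fails to calibrate
scores 0. An exhaustive-search twin evaluates every M-subset under the
same evaluator and serves as the test oracle on small pools.

The ranking criterion is the cross-validated trial accuracy **averaged
over flash counts 1..10** — the area under the accuracy-versus-flash-count
curve — rather than the accuracy at 10 flashes alone. Accuracy at a single
flash count takes only `n_trials + 1` distinct values, so with ~30 trials
whole blocks of candidates tie exactly and the montage-order tie-break,
not the data, would decide; the flash-count average is finer-grained and
less variable while measuring the same thing. Reported calibration
accuracies (and the tie-break, and the binomial test) remain accuracies at
the full flash count.

## Consensus selection over leave-one-trial-out folds

For N calibration trials, the subset is treated as a hyper-parameter and
fit by an N-fold procedure: each fold drops one trial and runs the full
greedy search on the remaining N − 1. Each electrode then receives, per
fold, the score `max(0, M - k + 1)` for its 1-based addition rank `k` (0
if unranked), scores are summed over folds, and the top M electrodes form
the consensus subset; ties at the M-th slot break by the better best rank
across folds, then montage order. The final SWLDA model is fit on all N
trials restricted to the consensus subset.

Each fold evaluates candidates under its own deterministically shuffled
cross-validation partition (seeded by the fold index). With a fixed
partition all N folds would repeat the same partition's accidents —
leave-one-out folds share N − 2 of their trials — and the consensus would
inherit, rather than average away, single-partition noise.

The holdout generalization experiment draws a seeded random 20-trial test
set from a ≥ 60-trial session, runs consensus selection (and a default-8
fit) on the 40 calibration trials, and reports calibration and held-out
testing accuracy for both subsets with the flash-count tie-break.

## Individual and group statistics

For one subject with `n` trials, `k_default` correct with the default
subset and `k_custom` correct with the custom subset, the default
performance is summarized by the maximum-likelihood binomial rate `p_hat =
k_default / n` and the one-sided p-value is `P(X >= k_custom)` under
`Binomial(n, p_hat)`, computed by direct summation of the probability mass
function. P-values are reported raw, with a Bonferroni count offered
alongside for judgment. Group results are summarized descriptively (mean
accuracies, mean paired improvement, percentile bootstrap confidence
interval over subjects, count of individually significant subjects);
mixed-effects modelling of group effects is intentionally out of scope.

## The synthetic-data generator

No participant EEG is distributed with the analyses this package
implements, so a seeded generator provides sessions with the statistical
structure the method assumes. Per trial it draws the target choice and the
flash order (each label once before any repeats); target epochs receive
the ERP signal; all epochs receive noise.

**Signal.** Each `component_spec` is a Gaussian deflection (polarity,
amplitude in µV, latency, temporal SD) weighted across channels by a
Gaussian spatial topography. A profile may have several topography foci,
and a component may be bound to one focus — real ERP subcomponents have
distinct topographies and latencies, and this is what makes several
electrodes genuinely, non-redundantly informative.

**Noise.** Per-channel `1/f^alpha`-shaped noise with SD `noise_sd`
(`pink_exponent` 1–1.2), optionally mixed across neighbouring channels
with a Gaussian spatial kernel (volume-conducted background), a global
common-mode process, and rare 80 µV movement-like transients
(`artifact_rate`).

**Presets.** `typical`: one broad centro-parietal focus (spread 1.0)
covering the default-8 sites, N200 (3.5 µV) + P300 (6 µV), 4 µV noise —
the default subset suffices and selection cannot help much.
`mild_atypical`: a somewhat restricted, slightly lateralized focus.
`severe_atypical`: three left-lateral foci at FC5, C5 and CP5 (spread
0.12, disjoint from the default-8), each carrying a biphasic N2–P3 complex
(3 µV deflections) with staggered latencies (180/310, 300/430, 420/550
ms), 8 µV sensor-local noise with a 1.2 spectral slope and 5% artifact
epochs. The staggered multi-focal design reflects the patchy, variably
timed reorganized activity described for users with severe early brain
lesions; the amplitudes were chosen once so that single-channel accuracy
is far from ceiling while the full custom subset calibrates well —
the regime in which subset membership actually matters. Cohorts jitter
each subject's foci (±0.06), spread (±10%), amplitudes (±15%), latencies
(±20 ms) and noise (±10%) around the preset, with per-subject seeds
derived from one master seed.

**What the generator does not emulate.** Epochs are simulated
independently, although the real inter-flash interval (~156–167 ms) is
much shorter than the 800 ms response window, so real epochs overlap
heavily; there is no biophysical head model, no eye or EMG artifact
physiology, and no session non-stationarity. Passing the end-to-end tests
therefore shows that the analysis chain recovers the structure it assumes,
not that it would behave identically on laboratory EEG.

## Problem sizes and numerical choices

The shipped studies use the sizes the analyses are designed around:
30-trial 256 Hz sessions for the severe-profile recovery study (20
subjects; leave-one-trial-out consensus over the full 32-channel pool),
60-trial 600 Hz sessions for the typical-profile null control (20
subjects; 40/20 calibration/testing split), and 200 noise-only subjects
for the chance-level check (run on the default-8 montage at 256 Hz — with
zero signal amplitude the channel count is immaterial to the chance
property). All randomness flows from explicit seeds; identical seeds give
bit-identical sessions, selections and reports.

Known limitations: the greedy search is myopic and, at accuracy ceiling,
later addition ranks carry little information (the consensus scores
absorb most of this, but subset members beyond the informative channels
are essentially arbitrary); the wrapper maximizes a cross-validated
criterion over many candidates, so selected-subset calibration accuracy
retains an optimistic selection bias that only held-out data can remove —
which is exactly why the generalization experiment exists.
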