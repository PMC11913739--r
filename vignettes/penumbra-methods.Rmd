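---
title: "Measuring single-neuron excitability against a propagating seizure wavefront"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-neuron excitability against a propagating seizure wavefront}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penumbra)
```

## The problem

In focal-onset seizures a slowly advancing *wavefront* separates the
intensely firing seizure *core* from the low-firing *penumbra*. The
surround-inhibition model holds that inhibitory neurons ahead of the
wavefront suppress penumbral territory, but firing rates alone cannot
distinguish "suppressed" from "not driven". All-optical interrogation —
simultaneous two-photon calcium imaging and targeted two-photon optogenetic
stimulation — resolves this by injecting a fixed, known perturbation into
chosen neurons and reading out the evoked calcium response: the response
magnitude is an operational measure of the neuron's instantaneous
excitability, and its spatial organization relative to the wavefront is the
quantity of interest.

`penumbra` implements the full analysis chain for such experiments in an
acute focal seizure model (local 4-AP injection, awake head-fixed mouse,
GCaMP indicator, soma-targeted opsin), and a seeded simulator that generates
complete synthetic experiments with known ground truth, so that every stage
of the chain is validated by parameter recovery rather than by eye.

## Data model

A `SeizureExperiment` extends `SummarizedExperiment`: rows are neurons
(segmented ROIs with centroids in micrometers, photostimulation-target and
inhibitory flags), columns are imaging frames (timestamps plus the
photostimulation-artifact exclusion mask), and assays are neurons x frames
matrices (`fluorescence`, optionally `deconvolved`, and `dff` added by
`addDff()`). Photostimulation trials, seizure intervals, and per-trial
wavefront annotations are DataFrame slots with accessors (`trials()`,
`seizures()`, `frontLines()`); simulated experiments also carry a ground
truth (`groundTruth()`).

## The analysis chain

**dF/F.** Each trace is normalized to its own mean, computed with
photostimulation-artifact and ictal frames removed: `(F - m)/m`. The
transform is scale invariant; a non-positive mean rejects the ROI.

**Trial states.** A trial is *baseline* before the convulsant injection,
*ictal* if its onset lies inside a seizure interval, *excluded* within a
0.5 s guard of a seizure boundary, otherwise *interictal*; interictal trials
within 30 s before an onset or after an offset carry *preictal*/*postictal*
sub-labels. The sub-labels refine interictal rather than replacing it, so
state-wise summaries can compare "all interictal" against the sub-periods.
Guard exclusion takes precedence over the sub-labels. A seizure already
running at recording start has an undefined onset: trials before its offset
are ictal, and it contributes no event to the phase analysis.

**Photostimulation responses.** The response magnitude of a trial is the
mean dF/F from the protocol offset to +500 ms minus the mean from -500 ms to
the protocol onset; frames flagged as artifact (including a neighbouring
trial's) are dropped from the windows. Single-trial responses are z-scored
to the same neuron's distribution of baseline-state responses (sample SD;
undefined when fewer than two baseline responses exist). Variability is
summarized per neuron and state as the coefficient of variation. Widefield
(one-photon) stimulation uses the same definition with the high-speed
shutter deployment/release as the window anchors, and the network decay
constant is the time for the mean-field trace to fall below 63% of its
post-stimulation maximum (trials that never return, e.g. stimulation-induced
seizures, are undefined and excluded).

**Wavefront geometry.** The wavefront at a trial is annotated as a straight
line through two points at least 100 um apart, plus a reference point
marking the penumbral side. Distances are signed perpendicular distances to
the infinite line, positive toward the penumbra. Excitability profiles are
rolling means over distance (40 um bins for target responses, 20 um for
neuropil, 5 um steps, t-based 95% intervals, bins with n < 5 flagged and
suppressed from displays). Non-targets are *proximal* at 0-100 um ahead of
the front and *distal* beyond 200 um.

The same machinery yields the neuropil counterpart of the target profile
(`neuropilProfile()`): annulus levels measured 0-250 ms before each trial,
z-scored per neuron to baseline trials, in 20 um rolling bins over wavefront
distance.

**Influence.** With 30-50 neurons stimulated simultaneously there are no
no-stimulation control trials, so each non-target's predicted response on a
trial is the mean response of all non-targets on that trial — legitimate
because non-target responses are strongly correlated within a trial (the
simulator reproduces this with a shared per-trial fluctuation and a common
network response). The influence of a trial on a non-target is its deviation
from this prediction divided by the across-trial SD of that deviation; the
construction is exactly invariant to per-trial offsets shared by all
non-targets. Influence is attributed to every target within 400 um of the
non-target, binned by pair distance; under ensemble stimulation the
attribution is associational, not single-target causal. Sham ("artificial")
trials at inter-trial midpoints provide a null.

**Phase locking.** Each seizure onset is assigned the signed time to its
nearest photostimulation trial, binned in 1 s bins (zero bin: -500 to
+500 ms), converted to an angle on the local inter-stimulus cycle, and
tested for concentration at 0 rad with the one-sided V-test
(`u = R cos(theta) * sqrt(2n)` against the upper normal tail). Bin-center
angles are used, matching the bin-then-test procedure; unbinned angles are
retained for sensitivity analysis.

**Recruitment timing.** Seizure-aligned traces (baseline window -1.5 to
-0.5 s before onset) are thresholded at a stated fraction (0.65 or 0.85) of
their within-seizure maximum; the delay is the first at-or-above frame, with
no sub-frame interpolation. The same rule applied to the 20-100 um annulus
neuropil around an inhibitory neuron (excluding other labelled somata)
gives the local-tissue recruitment time that the neuron's own delay is
compared against. The seizure-invasion time of a neuron is operationalized
as the last local minimum (after 3-frame smoothing) before the
within-seizure argmax of its raw trace — a deterministic stand-in for a
manual annotation.

## The simulator

Traces are built in dF/F units as: Poisson spontaneous transients convolved
with an exponential kernel (decay `transient_tau`); a sigmoidal rise to an
ictal plateau at each neuron's recruitment time (onset + projected distance /
speed, for a linear front of constant speed), decaying after seizure offset;
photostimulation-evoked transients on targets with amplitude
`stim_gain_interictal x gain_vs_front_distance(signed distance)`; coupled
responses on non-targets (kernel +w within 25 um, -w at 25-200 um); a common
network response on all neurons; a shared per-trial fluctuation multiplying
all evoked amplitudes; post-ictal multiplicative suppression; Gaussian
noise. Raw fluorescence is `f0 * (1 + signal)` with a large additive
artifact on stimulation frames (widefield trials instead darken the frames,
emulating closed PMT shutters). An LFP proxy oscillates strongly inside
seizure intervals. Stimulation can trigger seizures (`trigger_prob`) with
jittered onsets. Identical configurations and seeds give bit-identical
experiments.

### Key defaults and why

| parameter | default | rationale |
|---|---|---|
| `frame_rate` | 15 Hz | resonant-scanning rate at 1024x1024 |
| `fov` | 1000 x 1000 um | low-zoom two-photon field |
| `transient_rate`, `transient_amp`, `transient_tau` | 0.1 /s, 1 dF/F, 1 s | sparse awake-cortex events with GCaMP6s-like decay |
| `stim_gain_interictal` | 0.2 dF/F | ~20% dF/F evoked target response |
| `seizure_plateau` | 4 dF/F | ictal calcium far exceeds single transients |
| `recruit_rise_tau` | 0.1 s | sharp recruitment rise at the front |
| `wavefront_speed` | 300 um/s | mid-range of reported focal-seizure recruitment speeds; crosses the field in ~3 s, matching gradual FOV-wide recruitment over a few seconds |
| `gain_vs_front_distance` | 0.1 / 0.3 / 1.0 / 1.5 | recovery target encoding core suppression, proximal hypoexcitability, distal facilitation; magnitudes are free parameters |
| `coupling_weight` | 0.1 | short-range excitatory / mid-range inhibitory influence |
| `postictal_suppression` | 0.5 over 30 s | post-ictal activity depression |

## Benchmark design

The recovery benchmarks (`gainRecoveryConfig()`, etc.) fix the study
conditions used by the validation suite and the acceptance script; each
isolates one question.

*Gain profile* (`gainRecoveryConfig`): 40 targets, ~150 ictal trials over 75
seizures whose onsets carry a random phase against the 5 s trial grid
(on-grid onsets would sample each wavefront at the same few distances per
target and collapse the profile onto discrete points). Two deliberate
isolations: the ictal plateau is disabled, because under a constant-speed
front any target at small positive distance is, by construction, recruited
within a second of the trial, so the recruitment transient — an artifact of
the linear-front idealization rather than a property of the gain profile —
would dominate its response windows; and spontaneous transients are
disabled, because they add response-independent variance that dilutes the
z-scored contrast equally in every bin. Both mechanisms are exercised by the
other benchmarks. Seizure spacing always exceeds seizure duration plus the
post-ictal window, so suppression from one seizure never scales the next
seizure's early trials.

*Recruitment timing* (`recruitmentRecoveryConfig`): full dynamics. Two
deterministic biases bound the accuracy: thresholding a sigmoidal rise at
65% crosses `0.62 * recruit_rise_tau` after the true recruitment time, and
frame quantization adds about half a frame. For the neuron-vs-annulus
comparison the annulus trace reaches 65% of its maximum when about 65% of
the annulus area is recruited — 26 um past the center for the 20/100 um
annulus — so the null difference is approximately
`0.62 * recruit_rise_tau - 26 um / speed`; at the default rise time and
speed these nearly cancel (about -0.04 s, under one frame period), which is
why recruitment of inhibitory neurons simulated coincident with the front
reproduces the null result this comparison is meant to show.

*Influence* (`influenceBenchConfig`): a dense 500-neuron field, because the
20 um exclusion zone around each target leaves only 20-25 um pairs in the
excitatory coupling band. Spontaneous transients are disabled here too: their
positive skew biases the t-like influence ratio slightly negative everywhere,
which is a property of the trace model, not of the metric being calibrated.
The null calibration (zero coupling) keeps the shared fluctuation and global
network response on, so it genuinely tests that the trial-wise mean
prediction removes common components. Because each non-target's influence is
attributed to every nearby target, the net effect for a first-bin pair is
`+w` minus `w` times the Poisson-distributed count of mid-band targets; this
structural variance is irreducible at fixed density, so sign recovery for
the first bin is assessed on means pooled across seeded replicates.

*Phase locking* (`triggeredSeizureConfig`): every post-injection trial
outside a seizure triggers one (onset jitter 200 ms); calibration uses
uniform event times directly.

## Numerical conventions

Sample (n-1) standard deviations everywhere; undefined quantities are NA and
aggregations skip them with counts. Frames with timestamps inside
`[onset, offset]` of a trial are excluded (closed interval — conservative
against artifacts). Pre-windows are `[t-w, t)`, post-windows `(t, t+w]`.
Pixel membership uses the pixel center (annulus: `r_in <= d < r_out`; disks:
`d <= r`). The 20 um non-target exclusion is boundary-inclusive.
Cross-correlation ties break toward the smaller absolute lag. Recruitment
thresholds take the first at-or-above frame without interpolation. The 65%
versus 85% recruitment threshold is a required argument, never a hidden
default, because both conventions are in use for different questions.

## What the benchmarks do and do not show

Passing recovery on synthetic data shows the chain measures what it claims
under the stated generative model. Real recordings differ in ways the
simulator deliberately omits: wavefronts stall, curve and retreat rather
than advancing linearly at constant speed; motion artifacts and
segmentation errors are absent (motion correction and segmentation are
upstream of this package); calcium indicators low-pass true firing;
spontaneous activity is neither Poisson nor stationary; and opsin expression
is heterogeneous, so real evoked amplitudes vary across neurons beyond the
shared fluctuation modeled here. The benchmark problem sizes (for example
~150 ictal trials with 40 targets for the gain profile, 1000 replicates for
the phase calibration) were chosen to match the scale of a realistic
experimental campaign while keeping each benchmark in the minutes range.

## Limitations

The wavefront model is a straight line at constant speed; curvature and
stalling are out of scope, and the annotated line is taken as ground truth
rather than re-estimated from images. Seizure onset/offset marking is an
input (manual in practice), not an output. Single imaging plane; no
hardware emulation. With ensemble stimulation, influence attribution over
pairs is associational; the package never claims single-target causality.
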