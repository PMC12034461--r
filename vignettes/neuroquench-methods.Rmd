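---
title: "Methods: network-event detection, quench survival analysis, and the synthetic cohort generator"
author: "neuroquench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-event detection, quench survival analysis, and the synthetic cohort generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroquench)
```

This vignette is the package's own account of its models and the choices
behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The scientific setting

Mild neonatal hypoxia-ischaemia (HI) produces little immediate neuronal
death, yet neurons may still be lost days later. Two longitudinal
two-photon readouts quantify this at cellular resolution: population
GCaMP6s calcium imaging of cortical layer II/III (network activity) and
chronic tracking of constitutive mRuby fluorescence per soma (viability,
via *fluorophore quenching* — permanent loss of signal — as the
operational definition of death). The package implements the full analysis
chain for both readouts plus a forward simulator that generates cohorts
with the statistical structure those analyses assume, so that every stage
can be validated by parameter recovery against ground truth.

## Signal processing

**ΔF/F.** Per neuron, the baseline \(F_0(t)\) is a rolling 20th percentile
of the raw trace over a 60 s window (window clipped at the recording
edges), and \(\Delta F/F = (F - F_0)/F_0\). A percentile baseline tracks
slow drift while ignoring transients; 20%/60 s are conventional for slow
indicators at ~1 Hz sampling and are configurable
(`computeDFF(baselinePercentile, baselineWindowSec)`). The operation is
deterministic, invariant to positive rescaling of the raw trace, and
refuses all-zero traces (excluded with a warning) rather than emitting
NaNs. The rolling percentile is computed in C++ and matches
`stats::quantile(type = 7)` on every window exactly (tested against a
brute-force oracle).

**Activity raster.** The per-neuron noise scale \(\sigma\) is the median
absolute deviation scaled to a Gaussian SD — robust to the minority of
signal frames. Frames with \(\Delta F/F > k\sigma\) (strict inequality, so
values exactly at threshold are inactive — a deterministic tie-break), in
runs of at least `minFrames` consecutive frames, are active. Defaults
\(k = 3\), `minFrames = 2` (≈1.8 s at 1.1 Hz) suppress single-frame noise
excursions (two consecutive frames jointly exceeding \(3\sigma\) by chance
is vanishingly rare) while keeping single calcium transients, whose decay
spans 2–3 frames, detectable. If \(\sigma = 0\) (noiseless synthetic
input) an absolute ΔF/F floor (default 0.05) substitutes, with a message.
Raising \(k\) can only remove active frames (tested property).

## Network events and population metrics

The per-frame **co-active fraction** is the proportion of neurons active.
Synchrony thresholds in calcium-imaging pipelines are often chosen ad hoc
and are then hard to reproduce; the package instead uses an explicit,
seeded, data-driven null: each
neuron's active-frame train is independently circularly shifted (which
preserves every neuron's activity statistics and run structure while
destroying cross-neuron alignment), and the threshold \(\theta\) is the
99th percentile of the pooled shuffled co-active-fraction distribution
(1000 shuffles) with an absolute floor of 0.1. The floor guards the
degenerate case of a nearly silent raster, where any co-activity quantile
collapses to zero. All null settings are recorded in the event-set object.

**Events** are maximal runs of frames with fraction ≥ \(\theta\); runs
separated by at most `mergeGap = 1` frame are merged (a one-frame dip at
~1.1 Hz is within measurement jitter), then runs shorter than
`minFrames = 2` are dropped. Frames are 0-based and intervals half-open
\([on, off)\) throughout the package; durations are \((off - on)/\)frame
rate. An event's **participants** are the neurons active during ≥1 of its
frames (no fractional-overlap weighting — participation is a binary
membership per event, matching how per-neuron participation is defined).
Per animal, the metrics are event frequency (events/min), mean event
duration (s), and **network activation**, the mean over events of
participants / total neurons. With zero events, frequency is 0 and
duration/activation are reported missing, never zero. **Neuronal network
participation** is the fraction of the session's events containing the
neuron; with zero events it is missing for every neuron at that timepoint
and such records are excluded listwise from the mixed-effects stage.

## Quench calling and survival models

A neuron is **quenched** on the first observed day whose soma intensity is
at or below `kBg = 1.5` times the background level *and* remains at or
below it on all subsequent observed days within the persistence window
(default: all remaining days — the strict reading of "no signal
remained"). Dim-but-above-threshold days never trigger quench, and a
transient dip that recovers leads to censoring, not death. Day 0 is the
baseline identity — the neuron was selected as visible there — so quench
can only be called at day > 0 and event times lie in (0, censor day].
Censoring defaults to day 10 in vitro and day 11 in vivo.

Survival curves use the product-limit (Kaplan-Meier) estimator
(`survival::survfit`; verified against a hand-written product-limit oracle
to 1e-12). The group effect is a Cox proportional-hazards model with a
single binary covariate, maximised by Newton iterations with **Efron tie
handling** — ties are guaranteed by day-resolution times — via
`survival::coxph`, cross-checked in the tests against an independent
grid/`optimize` maximisation of the Efron partial likelihood written from
its definition. Variance is the **cluster-robust sandwich** over score
residuals grouped by animal ("clustering on mouse identifier"), chosen
over frailty fitting because it estimates the marginal group effect
without distributional assumptions on the cluster effect; the simulator
*generates* frailty but the analysis never fits one.

With only 6–8 animals per group (12–16 clusters) the plain sandwich
interval is anticonservative, so by default the package applies the
standard finite-cluster correction \(G/(G-1)\) to the sandwich and uses
\(t_{G-1}\) critical values for the 95% CI and p-value — the textbook
few-cluster practice. `clusterCorrection = FALSE` restores the raw
sandwich with normal quantiles (and reduces exactly to the unclustered
robust sandwich when every neuron is its own cluster — a tested identity).
Monotone-likelihood inputs (all events in one group) are rejected with a
diagnostic instead of returning a divergent estimate.

## Mixed-effects participation analysis

Participation is analysed untransformed on [0, 1] (as it is plotted in
practice; a logit version was considered and left out because the response
is a bounded fraction with few boundary values at these event counts —
the model is a comparison of means, not a forecasting device). The model
is a REML random-intercept fit, neurons nested within animals
(`participation ~ fixed effects + (1 | animal_id)` via `lmerTest`), with
Type III F tests. Denominator degrees of freedom default to
**Satterthwaite** — the method is not dictated by the design, and
Satterthwaite adapts between neuron- and animal-level information;
Kenward-Roger is available. If the random-intercept variance is singular
the model is refit as a fixed-effects-only linear model with a logged
downgrade (Type III via `car::Anova`), which also serves as the tested
degenerate equivalence: with no clustering structure the mixed model's
fixed effects equal ordinary least squares. A companion regression of
observed death day on baseline participation (random intercept per
animal) reports the slope, its F test and 95% CI, and refuses fewer than
3 observed deaths.

## The synthetic cohort generator

`CohortSpec` bundles every generator parameter; the presets are the
package's study conditions:

| parameter | default | meaning |
|---|---|---|
| frameRate, nFrames | 1.1 Hz, 500 | one session ≈ 7.6 min |
| eventRate | 3.9 /min | sham-baseline network-event rate |
| eventDurationMean, shape | 4.3 s, 7.2 | gamma durations; SD = mean/√shape ≈ 1.6 s |
| participationMean, dispersion | 0.52, 10 | beta-distributed per-neuron join probability |
| backgroundRate | 0.5 /min/neuron | asynchronous transients outside events |
| spikeAmplitude, amplitudeSdlog | 0.8 ΔF/F, 0.2 | burst-like GCaMP6s event response |
| noiseSd | 0.05 ΔF/F | additive Gaussian imaging noise |
| kernelRise, kernelDecay | 0.18 s, 1.5 s | double-exponential GCaMP6s kernel (literature-typical; configurable) |
| minEventGap | 3 s | refractory separation between events |
| neuronsRange | 18–85 (in vivo), 26–56 (in vitro) | neurons per animal |
| hazardSchedule | 0.005/d (d1–6), 0.02/d (d7–11) in vivo; 0.006/0.024 to d10 in vitro | late-rising daily hazard |
| hazardRatio | 3.232 (in vivo), 2.88 (in vitro) | injured vs control |
| frailtySd | 0.25 | lognormal per-animal log-hazard SD |

Durations are gamma (mean/shape parameterisation) so the reported
mean ± SD is reachable with a positive, right-skewed law. Participation
heterogeneity is beta with mean/concentration — per-neuron scatter is a
real feature of these data and the beta is the natural bounded choice.
Frailty is lognormal on the hazard scale; its SD was set by design-effect
back-calculation from the width of a published cluster-robust CI at this
design size (robust/naive SE ratio ≈ 1.4 at ~45 neurons per cluster
implies an intra-class correlation consistent with a log-hazard SD near
0.25). The 1 h injured-group multipliers (rate 0.35, duration 0.65,
participation 0.55) are placeholders for an acute suppression whose true
magnitudes are only available graphically; from 24 h onward all
multipliers are exactly 1 ("full recovery"), and that invariant is
tested. The late-rising hazard encodes death being most pronounced after
the first week; absolute levels were chosen to give plausible cumulative
death fractions (~12% control, ~35% injured by follow-up end), not fitted
to any measured curve.

**Event process.** Events form a stationary alternating-renewal process:
gamma durations, gaps = 3 s refractory + exponential, with the
exponential mean set so the long-run rate equals `eventRate`; the initial
condition is drawn from the equilibrium law (length-biased residual
durations), so the expected events/minute equals the configured rate
without burn-in (tested: mean rate over 50 recordings within 3 SE).
The refractory gap is physiological (synchronized networks need recovery
time) and prevents indicator tails from bridging adjacent events.

**Duration semantics and kernel inversion.** The configured event
duration refers to the *observable co-activity footprint*. A sustained
burst convolved with a 1.5 s-decay kernel stays above the detection
threshold for several frames after spiking stops, so the generator
inverts its own forward model: it predicts the effective per-frame
detection threshold under the default analysis — including the MAD
inflation caused by the signal duty cycle and the upward ΔF/F shift from
the percentile baseline, both solved numerically from the signal/noise
mixture distribution — computes the noiseless footprint of a W-frame
burst, and drives spikes for the smallest W whose footprint reaches the
drawn duration. Without this inversion the detected durations would be
biased upward by the indicator tail by construction, and the
duration-recovery check would be testing the kernel, not the detector.
Events too short to represent (below the single-spike footprint) are
floored at one driving frame.

**Survival arm.** Death days are drawn by inverse sampling of the
piecewise-constant cumulative hazard × group HR × animal frailty, on
integer days (ties intended). Intensity tracks put live neurons at a
bright level with lognormal day-to-day noise (sdlog 0.25) and occasional
dim-but-alive days (5% of days at 0.3×, still above the quench
threshold), and quenched neurons at the background level with tighter
noise (sdlog 0.15 — residual neuropil background varies less than a
living soma). These levels make the quench caller's job realistic but
solvable: the tested fidelity target is ≥95% exact death-day recovery.

**What the generator does not emulate.** No optical point-spread or
motion artifacts, no ROI segmentation (inputs are already
neuron-resolved traces), no z-drift or registration error, no
developmental desynchronization trend across days (timepoint multipliers
model injury, not maturation), no correlation between a neuron's
participation and its death day (fate-null by construction — which is
exactly what the null-calibration tests rely on). Passing recovery tests
therefore validates the analysis chain under the stated statistical
structure, not robustness to segmentation or registration failures in
real data.

## Numerical choices and degenerate inputs

Frames 0-based, intervals half-open, days integer, everywhere. Strict
inequality at the transient threshold; ≥ at the event threshold (the
shuffle quantile is itself an attained raster value, so ≥ keeps the
threshold-attaining frames that generated it). Merge-then-filter order in
event detection. The Efron/grid oracle agreement is asserted to 1e-6 on
the log HR (absolute scale); KM to 1e-12. Seeds: every stochastic
operation takes an explicit seed and restores the caller's RNG state
(`withr::with_seed`); identical (spec, seed) reproduce simulations
bit-identically (tested), and the pipeline's outputs are byte-identical
across reruns (tested via file checksums).

Problem sizes in the validation suite were chosen to exercise the study
designs at full size where it matters — 20 replicate 13-animal cohorts
for the detection-recovery checks, 100 replicate cohorts for mean-HR
recovery (plus 400 extra for CI-coverage assertions, where binomial noise
on a [90%, 99%] band is the limiting factor), 3 cohorts for quench
fidelity — and small fixtures everywhere a property is exact.

## Known limitations

* The shuffle-null synchrony threshold is a methodological choice, not a
  canonical standard; it is explicit, seeded and recorded in output
  metadata so results are comparable across runs.
* Averaging hazard-ratio estimates across replicates is upward-biased
  (Jensen: E[exp(β̂)] > exp(E[β̂])); the recovery checks compare that mean
  against the configured HR within a tolerance that absorbs this.
* The CLI's CSV interchange drops factor ordering; the `survival`
  subcommand re-levels control-like labels ("sham", "control") as the
  reference, and `coxClustered` documents that the first factor level is
  the reference.
* Acute 1 h suppression magnitudes are placeholders (graphical source);
  conclusions should not hinge on their exact values.
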