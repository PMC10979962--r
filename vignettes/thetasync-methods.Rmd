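---
title: "Methods: theta synchronization analysis and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: theta synchronization analysis and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thetasync)
```

`thetasync` analyses theta-band (5–12 Hz) synchronization in simultaneous
laminar recordings from hippocampus (HPC) and medial entorhinal cortex
(MEC): spectral power and coherence along the CA1–dentate and MEC1–3 axes,
spike–theta phase locking of classified single units, subpopulation
structure of MEC layer-3 excitatory cells, and a coherence-matched
subsampling analysis that dissociates local from long-range synchronization
deficits. This vignette explains the models and estimators, the parameters
that matter, the synthetic data the test suite runs on, and the numerical
and design choices made where the methods literature leaves latitude.

## The analysis window

Theta power and coherence are strongly state-dependent, so every estimate is
restricted to *analysis epochs*: maximal runs of locomotion longer than 3 s,
minus any seizure interval expanded by 600 s after its offset, with
fragments re-checked against the 3 s rule. Two conventions are deliberate:

* **Speed threshold.** Locomotion is speed > 2 cm/s (configurable). The
  threshold separates virtual-reality treadmill jitter (sub-cm/s) from
  running; results are insensitive to it in the 1–5 cm/s range because
  generated (and typical real) speed distributions are strongly bimodal.
* **No gap bridging.** "Continuous" movement is read literally: a single
  sub-threshold sample ends a bout. Bridging rules add a parameter with no
  principled default; with bimodal speeds they change little.

Epoch sets are half-open `[start, end)` real-valued second intervals with a
small normalized-interval algebra (union, intersection, difference); all
operations re-normalize so downstream code can assume sorted, disjoint
intervals.

## Spectral estimators

Power and coherence use multitaper estimates on 2 s windows cut from the
analysis epochs, with K = 5 Slepian tapers at time–bandwidth NW = 3
(±1.5 Hz resolution — appropriate for a 7 Hz-wide band). The band summary is
the **mean of magnitude coherence over 5–12 Hz**, not the value at the peak
frequency; the mean is more stable for narrowband signals whose carrier
drifts within the band. Window length, taper count, and the mean-vs-peak
summary are all exposed as arguments.

Slepian tapers are computed from the symmetric tridiagonal eigenproblem;
windows longer than 384 samples use spline interpolation of the 384-sample
solution followed by re-orthonormalization, the approach long used by
multitaper toolboxes. Tapers are cached per `(n, NW, K)`.

Practical estimator properties worth knowing:

* Magnitude coherence is biased upward at low true coherence when few
  windows are available (E|Ĉ| ≈ √(π/4M) under independence with M
  window–taper products). Per-bout estimates on 3–10 s bouts carry this
  bias; it affects *levels*, not the group contrasts the pipeline tests,
  because all groups are estimated identically.
* For phase-shifted copies of one oscillator the theoretical coherence is 1,
  but band bins with negligible power contribute roundoff-dominated ratios,
  so band-mean estimates settle near 0.99 rather than exactly 1.
  Self-coherence (x against x) is exactly 1.

Per-animal coherence matrices use one **representative channel per layer**
(the middle channel of the layer's contiguous block, configurable to
mean-over-channels), mirroring the reference-channel convention of the
phase-locking analysis. Group contrasts are Welch's *t* per layer pair with
α = 0.05 for two groups or 0.017 when three groups are compared pairwise;
no further multiplicity correction is applied beyond those printed alphas.

## Signal conditioning

Data are decimated to 1 kHz through cascaded ≤5× stages (8th-order
zero-phase Butterworth anti-alias at 80 % of each stage's Nyquist — cascading
keeps the IIR away from numerically fragile ultra-narrow cutoffs), notched
at 60 Hz (second-order, Q = 30, forward–backward), and theta-filtered with a
4th-order Butterworth bandpass applied forward–backward so the Hilbert phase
downstream carries no group delay. `signal::filtfilt` amplifies float
roundoff slightly (relative deviations ~1e-4); tests treat filter linearity
at that tolerance.

## Phase locking and circular statistics

The instantaneous theta phase is the analytic-signal angle of the
theta-filtered reference channel, wrapped to [0, 2π) with **0 at the
waveform peak and π at the trough** (reports render degrees). Reference
channels: CA1 theta = topmost pyramidal-layer channel, DG theta = middle
hilus channel, MEC theta = middle channel of the combined MEC2+MEC3 block.

Each unit's spikes inside the analysis epochs are mapped to phases by
nearest-sample lookup — flooring to the containing sample would lag every
spike by half a sample, a systematic μ bias of π·f/fs (≈ 0.1 rad at 8 Hz
and 250 Hz) that the recovery tests would expose. Units need at least 20
in-epoch spikes (the literature is silent; 20 keeps the Rayleigh test
meaningful while retaining sparse excitatory cells). μ is reported only for
units significant by the Rayleigh test at α = 0.05.

The circular statistics are self-contained:

* **Rayleigh test** with the standard small-sample-corrected p-value.
* **Two-sample Kuiper test**, V = max(F₁−F₂) + max(F₂−F₁), rotation
  invariant; p from the asymptotic Kuiper series at effective size
  n₁n₂/(n₁+n₂) with Stephens' correction, and a seeded 2000-shuffle
  permutation p below n = 50 per sample. The asymptotic form is slightly
  conservative in the far tail at moderate n (measured type-I ≈ 0.038 at
  α = 0.05, n = 100) but well calibrated at the α = 0.017 gate the
  sequential procedure actually uses; asymptotic and permutation p agree
  within 0.02 at n = 100.
* **Concentration test** (equality of von Mises κ), Fisher's three-regime
  construction: variance-stabilized angular transforms for pooled resultant
  r̄ < 0.45 and 0.45–0.70 (the stabilizer constants were verified by
  simulation), and a two-tailed F ratio on n−R for r̄ > 0.70. The variant
  choice (F-ratio rather than bootstrap) follows the classical construction;
  the test is mildly conservative (type-I 0.035–0.047 across regimes).
* **Sequential comparison**: group pairs are first gated by the Kuiper test
  at α = 0.017; only gated pairs receive the concentration test, starred
  against the ladder 0.017 / 0.003 / 0.0003 (strict inequalities).

## Unit classification

HPC units follow a fixed rule: excitatory iff rate < 8 Hz, complex spike
index > 0, mean autocorrelogram < 0.1, and trough-to-peak latency
(*c* index) > 0.26; inhibitory iff rate > 0.2 Hz and mean autocorrelogram
> 0.1; conflicts and failures are "unclassified". Three quantities in this
rule are under-specified in the methods literature and are resolved here
explicitly, all configurable:

* **Autocorrelogram normalization**: counts of spike-pair lags in 1 ms bins
  over ±50 ms (zero-lag excluded), divided by spike count — each bin is the
  expected number of follower spikes per reference spike, so a Poisson train
  at rate λ has mean bin value λ·(1 ms) and the 0.1 threshold separates
  Poisson-like sparse trains from fast-spiking/bursty ones.
* **Complex spike index**: burst amplitude attenuation — over consecutive
  spike pairs with inter-spike interval in (3, 15] ms,
  (n_decreasing − n_increasing)/n_pairs; 0 (flagged) when no such pairs.
* ***c* index units**: interpreted as milliseconds (0.26 ms sits in the
  usual narrow/broad waveform gap).

MEC units are split by seeded 1-D k-means (k = 2, 50 restarts) on the *c*
index; the narrow-waveform cluster is inhibitory. Degenerate inputs (< 4
units or identical latencies) leave all units unclassified with a warning.

## MEC3 trough/peak subclustering

MEC3 excitatory cells separate into trough-locked (μ near π) and peak-locked
(μ near 0) subpopulations of their locking to *local* MEC theta. Clustering
on raw (μ, r) is ill-defined at the 0/2π seam, so k-means runs on the
embedding (r·cos μ, r·sin μ) — the minimal faithful representation of the
two clustering parameters. Clustering is per experimental group, with labels
harmonized by each cluster's circular-mean phase (nearer π → trough-locked).
A forced split of a single phase cluster is flagged when the two cluster
means are separated by less than π/3; a silhouette threshold was considered
and rejected because silhouettes are scale-invariant and do not distinguish
a tight single cluster from a genuine bimodal split (measured 0.51 vs
0.61–0.67). At least 6 significantly locked units are required.

## Coherence-matched subsampling

Recordings are broken into running-bout bins (> 3 s); each bin receives a
multitaper coherence value for the three anchor pairs — cross-region
MEC2–Mol, within-HPC Hil–Pyr, within-MEC MEC2–MEC3. The control group's
**pooled per-bout values** define (mean, SD) — pooling is chosen over
per-animal means because the retention rule operates on bouts; the
alternative is selectable. Epileptic bouts within ±1 SD are retained;
animals with fewer than 5 retained bins (the operationalization of an
"insufficient bins" exclusion) are dropped from all subsampled comparisons.
Subsampled coherence is the mean of retained per-bout values; re-estimation
over concatenated retained bouts is available behind a flag (averaging is
the default because the retained objects *are* bout-level values).
Matching is verified by a one-way ANOVA on the matched anchor in the
subsample (must be non-significant); the other anchors are then re-tested on
the same retained bins. Jaccard overlap of retained bins between runs
matched on different anchors quantifies whether one network state drives all
anchors.

Two caveats follow from the selection rule itself. Retention selects on
*measured* bout coherence, so measurement noise leaks a small
regression-to-the-mean residual into the matched anchor (< 0.02 in the
simulated cohorts); and because control animals are not subsampled, their
own outlying bouts stay in the control mean. Both effects are visible only
when between-animal variance is unrealistically small.

## The synthetic cohort generator

The generator exists so that every stage has a ground truth. Its signal
model: channel *i* is

x_i(t) = A_i [ Σ_k √(γ_ik s_k(t)) cos(Θ_k(t) + φ_i) + √(1 − Σ_k γ_ik s_k(t)) cos(Θ_i(t) + φ_i) ] + η_i(t)

where Θ_k are shared theta sources (8 Hz carriers, AR(1) frequency drift
with 0.4 Hz s.d. and 2 s time constant), Θ_i a private oscillator of the
same spectrum, γ_ik the fraction of theta variance from source k, and η 1/f
noise of set RMS. Pairwise theta coherence then converges to
√(γ_ik γ_jk)·s_k as noise → 0 — a closed-form oracle. HPC layers load on
source H, MEC layers on M, and the Mol/MEC2 channels additionally on a
cross-region source X, giving the three anchor pairs independent knobs.

s_k(t) is a block-wise synchronization state (20 s blocks; 1 when
synchronized, 0.18 when desynchronized). Epileptic groups spend 45 % of
blocks desynchronized versus 5 % for controls — deficits are expressed as a
larger fraction of desynchronized time, which is exactly the structure the
subsampling analysis assumes ("an intact theta generator active in a subset
of time bins") and yields coherence deficits of realistic magnitude
(~0.15 on the 0–1 scale). In the **shared** mechanism one state series
drives all sources; in the **independent** mechanism each source has its
own. Animals differ by a log-normal (s.d. 0.06) multiplier on all loadings
and a ±0.04 jitter on the desynchronization probability — without
animal-level heterogeneity the group ANOVAs become implausibly sensitive,
flagging sub-0.02 residuals no real cohort could detect.

Spike trains are inhomogeneous Poisson with rate
λ(t) = λ̄·exp(κ cos(φ(t) − μ))/I₀(κ), realized by thinning a dominating
homogeneous process at λ̄·e^κ/I₀(κ). The I₀ normalization keeps the mean
rate independent of κ, so group effects on spike *timing* leave rates
unchanged — matching the empirical pattern that epileptic phenotypes alter
phase locking without rate changes. The expected spike-phase resultant is
I₁(κ)/I₀(κ). Unit populations draw preferred phases from von Mises
distributions whose concentration (κ_pop) controls across-cell phase
dispersion separately from within-cell locking (κ_spike); epileptic effect
multipliers disperse DG interneuron phases, reduce trough-locked MEC3
κ_spike at the late time point, and scale LM/Mol theta amplitude down.

Behavior alternates stillness with log-normal running bouts (median 10 s —
multi-second virtual-track traversals — so most bouts hold ≥ 5 analysis
windows); the generator returns its own ground-truth bout list. Seizures are
Poisson events (epileptic groups only).

**What the generator does not emulate** (so what passing tests do not show):
no dentate spikes, gamma, current-source density structure, spike waveforms
on the LFP, volume conduction, phase–amplitude coupling, electrode drift, or
non-stationary theta frequency beyond slow drift. Layer assignment in
synthetic sessions comes from the generator's channel map; the
feature-based `propose_layers()` heuristic (power peak → fissure, spike-band
RMS peak → pyramidal layer, ~180° phase reversal → CA1/DG boundary) is a
deliberately minimal stand-in for the multi-cue localization used on real
probes, is always overridable by an explicit map, and is tested only against
synthetic laminar signatures.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run, per stage: parameter
recovery at κ ∈ {0.5, 1, 2, 4} with 5 Hz units over 300 s (50 seeds);
Rayleigh calibration with 5000 uniform samples of n = 100; Kuiper and
concentration type-I over 1500–2000 simulated pairs at n = 100; coherence
oracles on 300 s two-channel sessions at γ ∈ {0.25, 0.49, 0.81};
subsampling nulls on 6 × 40 Gaussian bout values over ≥ 60 seeds; and the
dissociation scenarios on cohorts of 6 animals per group with 10-minute
sessions at 250 Hz (the multitaper estimator is statistically identical at
any rate ≥ 2× the band edge for fixed 2 s windows), 20 seeded replicates
per mechanism. These sizes were chosen so each check has comfortable
statistical margin while the full suite runs on one CPU in minutes.

## Known limitations

* The asymptotic two-sample Kuiper p is conservative in the far tail at
  moderate n; use the permutation path (`perm_threshold`) when exact far
  tails matter.
* Fisher's concentration test is approximate and mildly conservative; its
  low-concentration regime (r̄ < 0.45) has limited power by construction.
* Per-bout coherence on 1–3 window bouts is noisy and upward-biased at low
  coherence; inference is designed around group contrasts, not absolute
  levels.
* `propose_layers()` uses three cues only and should be reviewed channel by
  channel on real data.
* The pipeline assumes curated spike sorting; sorting itself, seizure
  detection, and histology are out of scope.
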