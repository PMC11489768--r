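---
title: "Methods: quantifying behavioral and dopamine-circuit responses to nicotine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying behavioral and dopamine-circuit responses to nicotine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicocircuit)
```

nicocircuit implements the quantitative pipeline behind a class of
multi-modal nicotine studies in mice: voluntary oral consumption in the
home cage, anxiety-like and reinforcement behavior, in vivo dopamine
single-unit responses, brain-wide cFos coactivation networks, synaptic
bouton morphology, and ex vivo synaptic physiology. Each module consumes a
simple text format (CSV or TIFF), and each has a seeded generator that
produces synthetic input with known ground truth, so the whole chain is
testable end to end without animal data. This vignette records the models,
the tunable parameters, and the design choices made where the underlying
procedures are conventionally under-specified.

## Two-bottle choice

Home-cage drinking is recorded as per-minute volume changes on two
bottles. The analysis chain is:

* **Artifact cleaning** (`clean_minutes()`): readings strictly above
  0.1 ml/min are physically implausible for a mouse and indicate leaks or
  sensor errors; they are removed (set missing), never interpolated —
  interpolation would invent volume. The comparison is strict, so a
  reading of exactly 0.1 ml is retained. The count of removed minutes is
  reported.
* **Session windows** (`session_windows()`): sessions run 20:00 to 14:00
  the next day, covering the active drinking period; bottle changes happen
  in the 14:00–20:00 off window. Intervals are half-open
  \[20:00, 14:00) to avoid double counting.
* **Preference** (`session_preference()`): 100 × test volume / total
  volume, with the test bottle resolved per session day from the label
  table (sides swap every two days). Preference is therefore invariant to
  the physical side, which the tests verify by permuting sides.
* **Dose** (`daily_dose()`): concentration (µg/ml) × volume (ml) / 1000 /
  (weight (g)/1000), i.e. mg/kg per session-day. Body weights measured
  every other day are linearly interpolated (smooth growth assumption);
  dates outside the measured range fall back to the nearest value and are
  flagged.
* **Side-bias exclusion** (`side_bias_filter()`): animals with a
  water-vs-water habituation side share below 20% or above 80% (strict
  inequalities; boundaries retained) cannot be scored for solution
  preference and are excluded.

The generator (`gen_drink_series()`) gates per-minute drinking bouts with
a von Mises-shaped circadian weight peaking one hour after dark onset
(concentration 3, putting roughly two thirds of intake into the dark
phase), draws bout volumes from a gamma distribution (mean ≈ 0.03 ml)
capped below the artifact threshold, and assigns each bout to the test
bottle with the programmed preference probability. Artifact minutes, when
requested, are drawn uniformly in (0.11, 0.5) ml. With eight sessions of
one animal, the recovered mean preference has a standard deviation of
about 2.5 percentage points around the programmed value — single-animal
recovery at the ±3-point level is therefore tight, and cohort-level
estimates (as in `analysis/02_drinking.R`) are correspondingly more
precise.

## Maze and place-preference scoring

The elevated O-maze trace is a frame-wise open/closed label sequence over
9 minutes, scored as open-arm percentages in three 3-minute blocks
(`eom_block_times()`); frames map to blocks by half-open intervals on
frame timestamps, and a short trace flags a partial final block rather
than silently rescaling. The injected minute precedes maze placement, so
blocks are timed from placement.

The CPP score (`cpp_score()`) is test minus pretest time in the
drug-paired chamber, in seconds. Unbiased group assignment
(`cpp_assign_unbiased()`) partitions animals so group-mean pretest biases
are as equal (and near zero) as possible: a greedy pass over animals
sorted by decreasing |bias| is polished by pairwise-swap hill climbing,
with deterministic seeded restarts from shuffled orders; the tests verify
the result is at least as balanced as the best of 10,000 random balanced
splits. Assignment only relabels animals.

## In vivo spike-train responses

Firing is quantified on overlapping 60-s windows stepped by 15 s
(`sliding_rate()`); windows are attributed by center and partial edge
windows are dropped, not renormalized. Each unit is rescaled to the mean
rate of the windows fully inside the 3 minutes before injection
(`normalize_to_baseline()`; zero-baseline units are excluded with a
reason). The response summary takes the maximum (activation) and minimum
(inhibition) normalized rate over windows whose center lies in
(injection, injection + 180 s] — whether the injection minute itself
belongs to the response window is conventionally unstated; the half-open
choice here excludes the injection instant. A unit is *flat* when both
excursions stay within 20 points of 100% (configurable); otherwise the
larger excursion decides the class. When saline and nicotine timecourses
are both present, the summary also reports the difference of the signed
maximum variation between the two injections.

Bursts use the classic dopamine-neuron interspike-interval rule — onset at
ISI < 80 ms, offset at ISI > 160 ms — which the field's burst literature
established and which primary papers typically cite rather than restate;
both thresholds are parameters. %SWB is 100 × spikes inside bursts /
spikes in the window, and the implementation is checked against an
independent segment-based enumeration on random trains.

`gen_spike_train()` produces a piecewise-constant-rate renewal process
(2 ms refractory) whose rate steps by ×(1 + magnitude) or
×(1 − magnitude) for a configurable response duration after injection.
With bursting disabled the ISI process is a small Markov renewal chain in
which an interval following a short one (< 80 ms) carries an 80 ms dead
time, and the exponential rate is solved (by root finding) so the
stationary mean ISI is exactly 1/rate: the no-burst contract holds by
construction without biasing segment rates. With bursting enabled, a
programmed fraction of spikes seed short-ISI followers (30–70 ms); the
planted within-burst fraction recorded in the ground truth is a
construction-side quantity — chance short ISIs of the carrier process add
genuine additional bursts, so it is a lower bound, not the detector's
expected output.

## cFos coactivation networks

Per-animal region counts are compared between groups with Welch's t test
per region, Benjamini–Hochberg q-values, and a log2 fold change with a
pseudo-count of 1 (`region_volcano()`); the volcano pass rule is exactly
fold change > 0 and −log10 p > 1.3 (p < 0.05). Coactivation is the
Pearson correlation of counts across the animals of one group (Spearman
by option); constant regions are flagged and their correlations set
missing. Hierarchical modules use average linkage on the distance 1 − r
(linkage is conventionally unreported; it is a parameter here), cut at
k = 4 by default.

Graph communities are found by Louvain modularity maximization on the
positively thresholded correlation matrix (negative correlations are
dropped because standard weighted modularity assumes nonnegative weights;
an |r| rule is available). The implementation runs seeded restarts and
keeps the best-Q partition, so results are deterministic given a seed; on
graphs of at most nine nodes the result is checked against exhaustive
partition enumeration and flagged if it is only a local optimum.

**Reorganization statistic.** How to test that community structure
*differs* between groups is genuinely open; this package formalizes it as
score = 1 − NMI between the two groups' partitions, with a null built by
permuting animal group labels and recomputing both partitions
(`community_reorganization()`). The permutation p-value is
(1 + #{perm ≥ obs}) / (1 + n). Both partitions use identical restart
seeds so optimizer randomness cancels; permutation tests remain exact for
any statistic computed identically on observed and permuted data. Two
properties of this statistic are worth knowing. First, at a 36-region,
4-module scale the score is effectively continuous and the test is well
calibrated (the acceptance suite measures a type-I error of about 5% over
200 null simulations); with very few regions the score is discrete and
the test turns conservative. Second, when the two groups carry *equally
strong but swapped* module structures, each permuted half tips to
whichever structure holds its sampling majority, so null scores reproduce
the observed score and the test correctly reports low power — it is
sensitive to asymmetric restructuring (e.g. modules dissolving or
merging in one group), which is the pattern of interest here. Per-region
change flags come from matching the two partitions by maximal overlap and
marking regions whose matched community differs.

## Bouton segmentation

Presynaptic boutons are segmented from 3D stacks (default voxel
0.05 × 0.05 × 0.2 µm) in two stages:

1. **Seeds** (`detect_seeds()`): 26-neighborhood local maxima at or above
   a threshold; plateaus resolve to the lowest linear index. The automatic
   threshold is background (histogram mode) + 6 robust SDs — at a million
   voxels, a 5-SD rule would already admit tens of noise maxima, and 6 SDs
   keeps the expected count near zero. Noise on the flat top of a spot can
   split one object into several nearby maxima, so seeds closer than
   0.4 µm (below a typical bouton diameter) are consolidated to the
   brightest.
2. **Growth** (`grow_boutons()`): for each seed the border intensity is
   the value enclosing the central 95% of a Gaussian section:
   background + exp(−z²/2)·(peak − background) with z = qnorm(0.975) ≈
   1.96, i.e. ≈ 0.146 of the peak above background. Because the factor is
   relative to each object's peak, boutons of similar size but different
   brightness segment at similar sizes. Growth is breadth-first over
   26-connectivity; a voxel joins only if it reaches the border
   threshold, is not brighter than the member voxel it extends (monotone
   descent), and is validated by an already-included neighbor closer to
   the seed — the third criterion suppresses single-voxel noise tendrils.
   Seeds are processed in decreasing peak order, so contested voxels go to
   the object reached by the brighter path. A per-axis Gaussian sigma is
   estimated from the seed's intensity profiles (anisotropic by default);
   degenerate profiles drop the seed. Objects outside 0.01–1.0 µm³
   (configurable) are discarded.

Counts are normalized to a standard 10 × 10 × 10 µm volume
(`bouton_density()`), making stacks of different sizes comparable.

## Patch-clamp currents

Decays are fitted from the post-peak segment by nonlinear least squares
(Levenberg–Marquardt) with one- and two-exponential models; the starting
time constant comes from the 1/e crossing of a lightly smoothed decay
(robust to tail noise). Model order is chosen by AICc, standing in for an
acquisition program's internal model choice; on seeded traces the
selector picks one term on noiseless mono-exponential input and finds the
second component when its amplitude share reaches 20% at SNR ≈ 20. The
weighted time constant is τw = (AF·τf + AS·τs)/(AF + AS) — a convex
combination of the two constants, invariant to joint amplitude rescaling,
and equal to τ for a one-term fit. Inward currents are stored negative;
all peaks and charges are reported as magnitudes.

Charge transfer is the trapezoidal integral of the baseline-subtracted
current magnitude over the onset-to-decay window (1 pA·s = 1 pC).
Paired-pulse ratio is peak2/peak1 of two transients 50 ms apart, each
against a local pre-stimulus baseline. The AMPA/NMDA ratio decomposes the
composite +40 mV sweep by point-wise subtraction of the DNQX-resistant
(NMDA) sweep and takes the ratio of component *peaks* — measuring NMDA at
a fixed latency instead is a common alternative; the peak convention is
flagged in the documentation. Pharmacological change (e.g. ifenprodil) is
100 × (AUC_drug − AUC_baseline)/AUC_baseline on averaged sweeps
normalized to a stable pre-drug baseline.

sEPSC detection is threshold-based (no template matching): the trace is
smoothed with a 1 ms boxcar, events cross baseline − 3 × the raw noise SD
(MAD estimate), and a Schmitt-trigger re-arm at 1.5 SD near baseline
prevents tail noise from re-triggering within one event; a 5 ms
refractory separates events. A raw 3-SD crossing rule without smoothing
fires on noise alone several hundred times per 30 s epoch at 10 kHz,
which is why the smoothing and hysteresis are part of the detector's
definition here.

## Statistical battery

`normality_gated_compare()` reproduces the gated pattern used across the
result tables: Shapiro–Wilk on pooled within-group residuals (residuals
rather than raw pooled data, so group mean differences do not masquerade
as non-normality; the choice is exposed) at α = 0.05 decides between the
parametric branch (Welch two-sample t, one-sample t against zero, Welch
ANOVA omnibus with pairwise Welch t) and the nonparametric branch
(Wilcoxon rank-sum with continuity correction, Wilcoxon signed-rank,
Kruskal–Wallis with pairwise Wilcoxon). Pairwise follow-ups are always
Holm-corrected. Ties make the exact Wilcoxon distribution unavailable, in
which case the normal approximation with continuity correction is used
and noted in the result. The two-sample engine holds its 5% level within
sampling error under both Gaussian and heavy-tailed nulls (2000
replicates each in the acceptance suite).

`mixed_anova()` fits the two-way mixed design (one between-subject, one
within-subject factor) with the standard error partitioning: the between
effect against between-subject error, the within effect and interaction
against subject-by-within error. Designs must be balanced and complete;
terms with numerically zero sums of squares report F = 0 rather than a
0/0 ratio of rounding noise. `adjust_pvalues()` exposes Holm and
Benjamini–Hochberg corrections, verified against their step definitions.

## What the generators do and do not emulate

The generators reproduce the *structure* each analysis stage depends on:
diurnal bout gating and side swaps; programmed block-wise zone occupancy;
piecewise-constant firing with refractoriness and optional bursts; latent
factor correlation blocks with multiplicative group shifts on rounded
counts; anisotropic Gaussian spots on constant background with white
noise; exponential-mixture transients with white noise. They do not
emulate lickometer bout microstructure, video-tracking artifacts,
non-stationary or oscillatory firing, count overdispersion beyond the
latent factor model, optical PSF side lobes or uneven illumination, or
correlated (1/f) recording noise. Passing recovery tests therefore shows
the implementations are correct under clean, known-truth conditions —
not that real data meet these assumptions.

## Problem sizes and numerical choices

The test and acceptance suites run at sizes chosen to make sampling error
small relative to the tolerances while staying desk-scale: 500 random
cases for the exact-Wilcoxon enumeration oracle; 100 random ≤ 8-node
graphs against exhaustive modularity search (Bell(8) = 4140 partitions);
200 random trains for the burst oracle; 200 synthetic units for response
classification; 200 null simulations × 99 permutations (36 regions,
4 modules, 10 animals/group) for reorganization calibration; 20 stacks ×
20 spots at SNR 10 for segmentation recovery; 2000 replicates per null
for the gated-engine level. Fixed seeds make every suite deterministic.
Numerical tie-breaks are documented at their definition: plateau maxima
resolve to the lowest linear index, Louvain restarts keep the first best
Q, contested voxels go to the brighter path, and boundary values (0.1 ml
readings, 20%/80% side shares, window edges) follow the strict/half-open
conventions stated above.

## Known limitations

* The reorganization statistic is one formalization among several; its
  power profile (strong for asymmetric restructuring, weak for balanced
  structure swaps) is intrinsic and documented above.
* Bouton segmentation assumes approximately Gaussian, sparsely packed
  objects; heavily overlapping or non-convex structures violate the
  monotone-descent criterion.
* sEPSC detection is amplitude-threshold based and will miss events
  below ~3 noise SD; template or deconvolution methods are out of scope.
* The mixed ANOVA requires complete balanced designs and does not
  implement sphericity corrections; the within factors used here have few
  levels and the gated nonparametric path covers strong violations.
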