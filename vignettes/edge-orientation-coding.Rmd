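---
title: "Edge-orientation coding in first-order tactile afferents: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-orientation coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(edgecode)
```

## The scientific problem

Human fingertips are innervated by fast-adapting (FA-1) and slow-adapting
(SA-1) type 1 afferents whose distal axons branch onto many
mechanoreceptive end organs. A single neuron therefore has a receptive
field with several highly sensitive zones ("subfields") spread over a few
millimetres of skin. When a raised edge is scanned across the fingertip,
the sequence in which the edge excites a neuron's subfields structures its
spike train, and that structure carries information about the edge's
orientation — potentially down to a few degrees, and potentially in a way
that survives changes in scanning speed if the spike train is read out in
*spatial* coordinates (each spike referenced to the position of the
stimulus on the skin when it occurred) rather than in time.

`edgecode` implements the full analysis pipeline for this question:

1. a generative subfield model of FA-1/SA-1 afferents scanned by oriented
   edges (so the pipeline runs with no external data),
2. segmentation of spike trains into 8 mm response windows registered to a
   drum position trace, with time-to-space conversion,
3. the three response measures — peak firing rate, mean firing rate, and
   the instantaneous firing-rate profile — in temporal and spatial domains,
4. ideal-observer leave-one-trial-out classification of edge orientation
   within and across scanning speeds,
5. Gaussian-kernel estimation of the spatial precision of spiking ("best
   kernel") and classification on convolved spike trains, and
6. aggregation: type x speed summaries, pairwise discrimination by angular
   difference, confusion matrices, and one-tailed above-chance tests with
   Bonferroni correction.

## The stimulus design

The drum layout fixes the experimental design: four edge orientations
(−10, −5, +5, +10 degrees relative to the axis perpendicular to the scan
direction), five presentations of each per drum rotation, lines at least
8 mm apart on a 59 mm diameter drum, three rotations per speed, and eight
scanning speeds (15, 20, 30, 45, 60, 90, 120, 180 mm/s), giving 15 trials
per orientation x speed. Available pairwise angular differences are 5
(two pairs), 10, 15 (two pairs) and 20 degrees.

## The generative model

Each model neuron is a set of Gaussian subfields inside an ellipse (major
axis 1.5 mm along the scan direction, minor axis 1 mm). The drive of an
edge with orientation θ whose scan-axis intercept is x is

    drive(x, θ) = Σ_i a_i exp(−d_i(x, θ)² / (2 σ_i²)),

where d_i is the perpendicular distance from subfield i to the line. An
edge passage produces an inhomogeneous Poisson train with rate

    r(t) = g (v/v₀)^β drive(v t + δ, θ) + r_bg,

followed by absolute-refractory thinning; δ ~ N(0, j²) is a per-trial
spatial offset (trial-to-trial jitter). Because the drive is a sum of
Gaussians in the intercept, the process is sampled exactly by
superposition: each subfield contributes a Poisson count of spikes with
Gaussian-distributed intercepts, plus uniform background spikes. Expected
spike count scales as (v/v₀)^(β−1): for 0 < β < 1, firing rates rise and
counts fall with speed, as in the recordings this design emulates.

### Default parameters and why

| parameter | FA-1 | SA-1 | rationale |
|---|---|---|---|
| subfield count | U{10..24} | U{5..12} | FA-1 fields have about twice as many subfields |
| subfield SD σ_i | U(15, 30) µm | same | spikes tightly locked to subfield positions (see below) |
| amplitude a_i | U(0.7, 1) | same | mild heterogeneity |
| gain g | U(1200, 2000) Hz | U(1100, 1800) Hz | counts ~22 → 5 and mean rates ~40 → 120 Hz from 15 to 180 mm/s |
| velocity exponent β | 0.6 | 0.2 | rate speed-sensitivity larger for FA-1 |
| reference speed v₀ | 30 mm/s | 30 mm/s | convention |
| background | 0.5 Hz | 0.5 Hz | sparse spontaneous/noise spikes |
| refractory | 1 ms | 1 ms | absolute refractory floor |
| jitter j | 30 µm | 30 µm | yields best kernels in the tens-of-µm range |

The narrow subfield drive deserves a comment. Real FA-1/SA-1 responses are
remarkably repeatable — spike timing is reliable at the millisecond scale,
which at these speeds corresponds to tens of micrometres. The generator
reproduces that regime by making each subfield crossing fire ~2 spikes
tightly localised around the subfield position (narrow σ_i, high gain), so
that the *trial jitter knob j* is the dominant trial-to-trial spatial
noise. With broad, weakly driven subfields the Poisson sampling scatter
would dominate instead, and the kernel-precision analysis would measure
the subfield width rather than the configured jitter — defeating the
purpose of j as the controllable precision parameter.

What the generator does **not** model: fingertip continuum mechanics
(viscoelasticity, anisotropy, ridge-level deformation), the physical width
of the raised line (the edge is an infinite zero-width line; responses to
such stimuli are dominated by the leading edge), interactions between
neighbouring lines, and any non-Poisson spike-generation dynamics beyond
the absolute refractory period. Passing tests on synthetic data therefore
show that the *analysis* behaves as intended under the stated statistical
structure — not that real skin obeys this model.

## Segmentation and registration

Each line passage is cut to an 8 mm response window (the minimum line
spacing). The window for a given line is centred on the spike-density
centre of mass of the neuron's pooled response to that line (all speeds,
rotations and trials), falling back to the nominal line position when
fewer than 10 pooled spikes exist; the centre is clamped so adjacent
windows can never overlap. Using one centre per neuron x line, shared
across speeds, registers spatial-domain responses across speeds without
ever using trial identity — so registration cannot leak class
information. Windows are closed at both ends (a spike exactly at 0 or
8000 µm belongs to the window; a 1e-6 µm numerical guard absorbs float
error). Trials with fewer than two spikes are flagged; their peak rate is
0 and their profiles all-zero, keeping every classifier total.

Window traversal durations are measured from the drum trace (inverse
interpolation of the positions of the window edges), not assumed from the
speed label.

## Response measures

* **Peak rate**: reciprocal of the shortest inter-spike interval.
* **Mean rate**: spike count / measured window traversal duration.
* **Firing-rate profile**: the reciprocal of each inter-spike interval,
  held constant over that interval (left-closed, right-open), zero outside
  the spikes, sampled on a uniform grid — 1 ms temporal, 10 µm spatial by
  default (the spatial step is ~3x the 3 µm drum encoder resolution). In
  the spatial domain the interval is measured in µm and converted to Hz
  via the trial's traversal speed, so for a constant-speed trace the
  spatial profile is an exact reparametrisation of the temporal one.

## Ideal-observer classification

Every classifier is leave-one-trial-out with strict-argmax decisions:

* The held-out trial's same-orientation reference is the mean (intensity)
  or mean correlation (profiles) of its remaining 14 trials.
* Each *other* orientation's reference uses 14 of its 15 trials, dropping
  the trial with the same (rotation, presentation) slot as the held-out
  trial — deterministic, balanced, and resampling-free.
* Ties count as incorrect. Together with defining the correlation of a
  zero-variance signal as 0, empty trials are always misclassified —
  conservative and total.
* Across speeds, the trial at the core speed is compared against the full
  15-trial references at every other speed (the held-out trial is at a
  different speed, so hold-out is automatic); one decision per (trial,
  other speed), pooled per core speed.
* Correlations are zero-lag Pearson on registered common-grid profiles;
  window registration by drum position makes a lag search redundant.

**Temporal-domain cross-speed comparison.** Profiles at different speeds
have different durations. They are compared centre-aligned on the absolute
1 ms grid and truncated to the shorter duration. Centre alignment (rather
than start alignment) is used because the response window is centred on
the response's spatial centre of mass, so the response mass sits mid-window
at every speed; start-aligned truncation would leave distant speed pairs
comparing empty stretches of signal, turning every such decision into a
degenerate tie. No duration rescaling is applied — rescaling time by the
speed ratio would covertly re-create the spatial domain and void the
temporal-vs-spatial contrast that the analysis exists to test.

**Speed normalisation.** The intensity classifiers can divide every value
by a population speed-intensity line (OLS of per-speed population mean
intensity on speed, fitted per neuron type) to test whether knowledge of
the population-level speed effect rescues intensity-based invariance.

## Kernel precision

Spatial spike trains are convolved with unit-mass Gaussians with SDs on a
doubling grid, 5-1280 µm (the grid step is min(10, σ/2) µm, floored at
2 µm, guarding resolution). For each kernel and core speed the mean
squared Pearson correlation (R², matching how such curves are usually
displayed; plain r available by flag) is computed over cross-speed trial
pairs with the same vs with different orientations, weighting each trial
pair equally and excluding within-speed pairs. The difference follows an
inverted-U in log σ: tiny kernels are defeated by trial-to-trial jitter,
huge kernels blur away all stimulus structure. The argmax is the **best
kernel** (exact ties go to the smaller σ — reporting finer precision only
on exact ties); a log-parabolic refinement through the peak and its
neighbours is available (`interpolate = TRUE`) and is used in the
jitter-recovery analysis, where sub-octave resolution matters. Neurons
with entirely flat curves (no spikes) are flagged and excluded from
summaries. Each neuron is summarised by its mean best kernel across
speeds.

The **jitter-recovery experiment** shipped in the tests varies only the
jitter knob (10-160 µm, six neurons per level) while holding the nuisance
hyperparameters fixed at the richest FA-1 configuration (24 subfields,
σ_i = 20 µm, gain 2000 Hz) — the standard parameter-recovery design: with
full neuron-to-neuron heterogeneity, variation in subfield geometry masks
adjacent jitter levels, and recovery power grows with the amount of
response structure available to correlate. At the largest jitter (160 µm,
pair misalignment ~226 µm) the same-vs-different contrast is close to
destroyed and the estimate becomes unstable for occasional layouts — an
inherent breakdown of the correlation-difference estimator, worth knowing
when interpreting large best kernels. Unimodality of the difference
curves is assessed as
rise-then-fall around the argmax with violations tolerated up to 5% of
the curve amplitude (the noise floor of an R² difference of order 0.01).

**Equivalent sinusoidal period.** A Gaussian bump of SD σ closely
resembles one cycle of a raised cosine. `gaussian_to_period()` returns the
period P minimising the integrated squared difference between
exp(−x²/2σ²) and (1 + cos(2πx/P))/2 over one period. The conversion is
exactly linear (P = cσ, c ≈ 4.92, determined once by numerical
minimisation and cached), so a type-averaged best kernel of ~70 µm maps
to a period of ~0.34 mm — the scale of a single papillary ridge.

## Aggregation and inference

`aggregate_results()` gives group means with SEM across neurons and
optional chance-subtracted and arcsine-square-root transforms.
`above_chance_test()` applies per-group one-tailed one-sample t-tests
against chance with Bonferroni correction over the speeds tested;
zero-variance groups are flagged and decided by sign. Repeated-measures
ANOVA machinery is intentionally not reimplemented — the per-neuron tables
are shaped for standard ANOVA tooling.

## Numerical choices and degenerate inputs

* Window boundary closed at both ends, with a 1e-6 µm float guard.
* Zero-variance signals: correlation defined as 0; combined with strict
  argmax, degenerate trials never classify correctly.
* Best-kernel ties: smaller σ. Confusion matrices split tied assignment
  mass uniformly so every block stays row-stochastic.
* Profile value on an interval is left-closed right-open; profiles are
  zero outside [first spike, last spike].
* Smoothing grid step ≤ σ/2 enforced; convolution conserves spike count
  to <1% away from window edges.
* All simulation is reproducible from the configuration seed; canonical
  datasets regenerate byte-identically.

## Problem sizes used in the shipped tests

The test suite and analysis scripts use reference configurations of 1-8
neurons for calibration checks (full 4 x 8 x 15 design each; shuffled-label
chance calibration with 8 neurons), 30 neurons for jitter recovery, and a
4 + 4 neuron dataset for the worked pipeline. These sizes give
Monte-Carlo standard errors small enough for 3-SE calibration bounds while
keeping the full suite fast; all of them are configuration arguments, so
larger studies are one `sim_config()` call away.

## Known limitations

* The simulator's spike trains are Poisson-with-refractoriness; real
  afferent intensity dynamics (burst adaptation, leading/trailing edge
  asymmetries) are not modelled.
* Registration by response centre of mass assumes the response is
  unimodal at the window scale; severely multimodal responses could
  off-centre the window (the clamp bounds the damage to ±0.6 mm with the
  default layout).
* The temporal-domain cross-speed comparison is one of several defensible
  conventions (alignment and truncation choices); the package fixes one
  and documents it rather than searching over conventions.
* Peak firing rate in the generator is refractory-bounded and therefore
  rises only weakly with speed; counts and mean rates carry the speed
  dependence.
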