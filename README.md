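# edgecode

Analysis pipeline for **fine edge-orientation coding by single first-order
tactile afferents**. Human fingertips are innervated by fast-adapting
(FA-1) and slow-adapting (SA-1) type 1 neurons whose distal axons branch
onto many mechanoreceptive end organs, giving each neuron a receptive
field with several sensitive zones ("subfields"). When a raised edge is
scanned across the skin, the sequence in which it excites those subfields
structures the spike train. `edgecode` asks how much information a single
neuron's response carries about fine edge orientation differences
(5–20°), how that depends on scanning speed (15–180 mm/s), and whether the
information survives speed changes when spikes are read out in *spatial*
coordinates (referenced to the stimulus position on the skin) instead of
time.

The package provides, as tested R functions:

* **Generative subfield model** — afferents as sums of Gaussian subfields;
  an edge at orientation θ with scan-axis intercept x drives the neuron by
  `Σᵢ aᵢ exp(−dᵢ(x, θ)²/2σᵢ²)` (dᵢ = perpendicular distance to the line);
  spiking is inhomogeneous Poisson with rate
  `g (v/v₀)^β · drive + background`, refractory-thinned, with per-trial
  spatial jitter `δ ~ N(0, j²)`. Counts fall and rates rise with speed for
  0 < β < 1; spatial structure is speed invariant up to j.
* **Data model** — canonical on-disk format (per-neuron `meta.json`,
  `spikes.csv`, `drum.csv`), drum-trace time→space conversion, and
  segmentation into 8 mm response windows registered by response centre of
  mass.
* **Response measures** — peak rate (1 / shortest inter-spike interval),
  mean rate (count / measured window duration), and piecewise-constant
  instantaneous firing-rate profiles in temporal or spatial coordinates.
* **Ideal-observer classification** — leave-one-trial-out, strict argmax;
  within one speed or across speeds (one decision per trial × other
  speed); intensity-based, profile-based (temporal or spatial domain), and
  on Gaussian-convolved spike trains; optional population speed
  normalisation; pairwise discrimination by angular difference; confusion
  matrices. Chance is 1/4 (four-way) or 1/2 (pairwise).
* **Spatial precision ("best kernel")** — sweep Gaussian kernels
  (5–1280 µm), correlate convolved trains across speeds, and find the SD
  maximising the same-minus-different orientation R² difference; convert a
  Gaussian SD to its equivalent sinusoidal period (`P ≈ 4.92 σ`).
* **Reporting** — type × speed summaries with SEM, arcsine transforms, and
  one-tailed above-chance t-tests with Bonferroni correction.

## Worked example

The `analysis/` scripts run the whole study on a synthetic dataset
(4 FA-1 + 4 SA-1 model neurons, 4 orientations × 8 speeds × 15 trials):

```sh
Rscript analysis/01_simulate.R         # writes results/dataset
Rscript analysis/02_features.R         # intensity measures
Rscript analysis/03_within_speed.R     # within-speed classification
Rscript analysis/04_across_speed.R     # speed-invariance contrast
Rscript analysis/05_kernel_precision.R # best-kernel estimation
Rscript analysis/06_convolved.R        # convolved-train classification
```

`02_features.R` reproduces the hallmark speed dependence — FA-1 spike
counts fall from 23.0 to 5.8 per passage between 15 and 180 mm/s while
mean rate rises from 43 to 131 Hz. `03_within_speed.R` shows that rate
profiles beat intensity measures within a speed (FA-1: 0.62 vs 0.28–0.32
proportion correct, chance 0.25; SA-1: 0.50 vs 0.25–0.27).
`04_across_speed.R` makes the central contrast: across speeds, temporal
profiles and intensity measures sit near chance (≈0.25–0.27) while
spatial-domain profiles remain informative (up to 0.45 at low core
speeds). `05_kernel_precision.R` prints the inverted-U correlation
difference curve (peaking at σ = 40 µm on this dataset, mean best kernels
42.5 µm FA-1 / 50.0 µm SA-1) and the equivalent sinusoidal period
(0.23 mm here). `06_convolved.R` shows pairwise accuracy growing with
angular difference (SA-1: 0.72 at 5° to 0.93 at 20°, chance 0.5) and
above-chance discrimination of 5° differences at almost every speed.

A minimal in-session example:

```r
library(edgecode)
dat <- generate_dataset(sim_config(n_fa = 1, n_sa = 0, seed = 42))
ts  <- segment_trials(dat$records[[1]])
profile_classify_across(ts, core_v = 30, domain = "spatial")$accuracy
#> [1] 0.6809524   # vs 0.25 chance; "temporal" gives 0.186 for this neuron
bk <- best_kernel(correlation_curves(ts))
bk$per_neuron$mean_best_sigma_um
#> [1] 40
```

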