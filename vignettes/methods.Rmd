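---
title: "Methods: synthetic force data, segmentation and recognition models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic force data, segmentation and recognition models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`forcepsml` analyses tool–tissue interaction forces recorded by a
sensorized bipolar forceps at 20 Hz on two channels (left and right
prong). Three models form the pipeline:

1. **T-U-Net** — a 1D U-Net that classifies every sample of a force trace
   as ON (tool actively applied to tissue) or OFF (idle), from which
   continuous force-ON blocks are extracted;
2. **FTFIT** — an InceptionTime-style convolutional classifier over
   200-point force windows, optionally augmented with a third channel that
   encodes hand-crafted segment features, used for surgeon-skill
   (Expert/Novice) and surgical-task (Coagulation vs non-Coagulation)
   recognition, with LSTM and XGBoost baselines and a hybrid logistic head
   on learned-plus-engineered features;
3. a **29-feature extractor** for force segments, with ranking utilities
   and the four-feature dashboard subset (Duration Force, Range Force,
   Entropy, Heterogeneity).

Operating-room recordings are not distributable, so the package ships a
seeded synthetic generator whose statistical structure follows the
published dataset statistics; all benchmarks in the test suite and the
acceptance script run on this generator.

# The synthetic generator

A recording alternates idle gaps and active segments. Design choices, in
the order they matter:

* **Task mix.** Segment tasks are drawn from the five-task vocabulary
  (Coagulation, Manipulating, Pulling, Retracting, Dissecting) with
  probabilities 1170/323/316/149/127 over 2085 — the normalized census of
  the published segment table — i.e. 56.1% Coagulation.
* **Duration law.** Durations are lognormal, the natural choice for a
  positively skewed, strictly positive duration distribution, with (μ, σ)
  solved analytically from the configured arithmetic mean and SD.
  Coagulation uses mean 12.1 s, SD 7.2 s; the four other tasks use mean
  12.1/1.58 ≈ 7.66 s, making Coagulation ~58% longer on average. No SD is
  published for non-Coagulation tasks; the package fixes 4.0 s, a
  realistic spread for sub-10-second surgical maneuvers. Durations are
  clipped at 1 s.
* **Skill neutrality of durations.** Skill effects (variance multiplier
  1.35, broadband noise SD 0.04 N and transient rate 0.25 /s for Novice;
  identity for Expert) perturb only the waveform, never the segment
  length, so Expert and Novice duration distributions coincide by
  construction — mirroring the published 0.8% (i.e. negligible) duration
  gap between skill groups, and the near-indistinguishability of skill
  classes on engineered features. Effect sizes were chosen once so that
  feature distributions overlap heavily across skill.
* **Waveforms.** Each task has a characteristic envelope: Coagulation a
  smooth rise/plateau/fall grasp with a low-amplitude tremor at 8–9.5 Hz
  (kept below the 10 Hz Nyquist limit of 20 Hz sampling); Pulling a
  ramp-and-hold; Retracting a long low-variance hold; Dissecting short
  spiky bursts; Manipulating irregular low-force wandering. The two
  prongs share a common waveform plus independent noise scaled so their
  Pearson correlation matches the configured target (0.9 by default).
* **Amplitudes.** No force-amplitude statistics are published in newtons;
  plateau ranges of roughly 0.2–2.5 N per task were fixed once, consistent
  with sub-3 N bipolar tip forces.
* **Idle gaps.** Exponential with mean 8 s; no idle statistics are
  published, and the value is configurable.

What the generator deliberately does **not** model: electro-cautery
artifacts, tissue mechanics, hand kinematics, inter-surgeon
idiosyncrasies, or session-level drift. Passing benchmarks on this
generator therefore demonstrates that the pipeline's machinery —
segmentation, feature plumbing, training, evaluation — works end to end
on data with the published first-order statistics; it does not certify
performance on real operating-room recordings.

# Preprocessing conventions

* Standardization removes the per-channel mean and scales to unit
  variance, with the **population** SD, fitted on training data only;
  validation and test partitions reuse training statistics (no leakage,
  asserted in the tests).
* Windows are non-overlapping by default (stride = L); 224 points for
  segmentation, 200 for recognition. The 200-point window corresponds to
  the ~10 s average segment duration at 20 Hz.
* Idle balancing trims every OFF run longer than 224 samples down to 224
  by deleting its central portion, preserving the OFF context at both ON
  boundaries.
* The nested split holds out 20% as test, then 20% of the remainder as
  validation: 64/16/20 overall, exact to ±1 item, seeded. Splits are
  segment-random; a grouped-by-case mode is intentionally absent at this
  scale.
* For task recognition, Coagulation is subsampled at fraction 0.5
  **before** splitting, matching the published balancing order.
* Segment-to-window fitting: longer segments are center-cropped, shorter
  ones edge-padded (boundary value repeated) symmetrically.
* The engineered-feature channel places the K standardized feature values
  at equally spaced abscissae across the window and interpolates to L
  points. The interpolation order is an integer knob (0 = step,
  1 = linear, default 3 = cubic spline with endpoint-held boundaries);
  the published description of the order selection is not interpretable
  as an algorithm, so the package declares cubic as its default and
  records the choice in the manifest. One combined channel (the "third
  signal") is the default rather than K separate channels.

# The 29 features

The exact published feature table is not available; the package freezes a
canonical list assembled from the named features plus the standard
time-series-features canon, computed on the mean of the two prongs except
the two explicit inter-prong descriptors:

moments/extrema (Duration, Mean, Median, Max, Minimum, Range, SD, IQR,
RMS, Skewness, excess Kurtosis, Coefficient of Variance); spectral
descriptors (Entropy = Shannon entropy of the normalized periodogram
scaled by log bin count, in [0,1]; Dominant Frequency; Spectral
Centroid); tiled-window irregularity (Stability = variance of 20-sample
tile means; Lumpiness = variance of tile variances); Heterogeneity =
ARCH-effect R² of a squared-residual autoregression (lag 12, shrunk for
short segments); Spikiness = variance of leave-one-out variances of the
detrended series; trend structure from orthogonal-polynomial regression
on time (Trend Strength, Linearity, Curvature); autocorrelation (ACF1,
First Autocorrelation Zero in samples); run/count statistics (Flat
Spots over 10 amplitude bins, mean-Crossing Points, Peak Count); and the
prong pair (Pearson Prong Correlation, Prong Asymmetry = mean |L−R|).

Degenerate inputs are defined, not rejected: a constant segment has
entropy 0, CV 0, skewness/kurtosis 0, correlation 0. All features are
guaranteed finite.

# Neural networks

No deep-learning framework is part of the package's dependency set; the
networks are trained by a compact engine built on BLAS matrix products
(im2col convolutions), with hand-derived backward passes verified against
numeric gradients in the test suite, Adam optimization, batch
normalization, and early stopping that restores the
minimum-validation-loss weights. Training is bit-deterministic for a
fixed seed on a single thread: initialization, batch order and all
stochastic draws come from the seeded R RNG.

**T-U-Net.** Three pooling levels (224 → 28 at the bottleneck), two
kernel-3 convolutions + batch norm + ReLU per level, filters doubling
from the base size 16, learned ×2 upsampling (transposed convolution),
skip concatenation, and a per-time-point 2-class softmax head. Published
hyperparameters are the defaults: learning rate 0.001, window 224, batch
128, filter size 16. Depth 3 is the package's choice; the published
description fixes only "encoder and decoder".

**FTFIT.** Inception modules with a 1-wide bottleneck, parallel
convolutions with kernels {10, 20, 40}, a max-pool→1-wide-conv branch,
concatenation, batch norm and ReLU; a residual shortcut joins every third
module; global average pooling produces the embedding feeding both the
softmax head and the hybrid logistic classifier. Depth 6 (skill) and 12
(task) with learning rates 0.001 and 0.01 are the published settings; the
**branch width defaults to 8 filters** (32-dimensional embedding), the
package's CPU-scale choice — the 32-filter width typical of InceptionTime
implementations is reachable through the config but costs roughly 16×
more compute per module, which single-threaded BLAS cannot sustain at
interactive scale. A single network is trained per run; ensembling is a
config knob defaulting to 1.

**LSTM baseline.** 2 stacked layers × 32 units (declared default; no
published topology exists), final hidden state → dense softmax.

**Post-processing.** Point-wise probabilities are binarized at 0.5; ON
runs separated by gaps ≤ 10 samples (0.5 s) are merged, and merged runs
shorter than 40 samples (2 s) discarded. Both thresholds are knobs; the
published pipeline states only that blocks must meet "length
requirements". The implementation is verified against an exhaustive
run-length oracle over all 4096 masks of length 12 for nine parameter
combinations.

# Evaluation

Metrics follow the published bundle: accuracy, sensitivity (positive
recall), specificity, per-class and support-weighted F1, macro-AUC
(unweighted mean of one-vs-rest AUCs), average precision, ROC/PR points,
and stratified 5-fold cross-validation. AUC uses trapezoidal ROC
integration with tied scores grouped, which equals the exhaustive
pairwise-concordance definition (ties counting one half) — asserted
against a brute-force oracle in the tests. The two-way feature ANOVA is
additive (no interaction), with drop-one F tests so each factor is
adjusted for the other. The gauge report maps dashboard names to
features: Average Force Duration → Duration Force, Range of Forces →
Range Force, Force Variability → segment SD, Force Uncertainty →
Entropy; the mapping is declared here because the dashboard naming never
formally equates them, and it is configurable in source.

# Benchmark scales and expected results

The test suite and `scripts/acceptance.R` use desk scales chosen as the
package's reference experiments:

* duration calibration: 50,000 draws (moments within Monte-Carlo error of
  12.1/7.2 s) and 10,000 segments (task gap ≈ 58%, skill gap < 1%);
* segmentation: 400 windows of 224 points, seed-driven, ≤ 30 epochs,
  64/16/20 split — held-out point-wise weighted F1 ≥ 0.95;
* task recognition: 1,000 generated segments (727 after Coagulation
  subsampling), FTFIT depth 6 with the subset-1 feature channel,
  ≤ 30 epochs — held-out macro-AUC ≥ 0.89, and above the LSTM baseline
  trained on the same split.

On synthetic data these margins are comfortable (the task benchmark
typically saturates near AUC 1.0) because the generator's task signatures
are cleaner than operating-room data; the published values act as lower
bounds that the synthetic analog must meet, not as quantities to
reproduce exactly.

# Known limitations

* The synthetic generator is a first-order emulation; no claim is made
  about real-data performance.
* The exact published feature definitions (supplementary table) are
  unavailable; the canonical list above is frozen and documented instead.
* Skill classification on default synthetic data is close to chance *by
  design* (skill effects are small and duration-neutral); the pipeline
  exposes the machinery rather than an artificial skill signal.
* Networks run on a single thread; widths are CPU-scale defaults and all
  size knobs are exposed in the configs.
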