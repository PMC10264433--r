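# forcepsml

Machine learning for **tool–tissue interaction forces** recorded by a
sensorized bipolar forceps. During microsurgery the two prongs of the
forceps apply forces to tissue in short active bursts — grasping a vessel
to coagulate it, pulling, retracting, dissecting — separated by idle
periods. `forcepsml` turns a raw two-channel 20 Hz force trace into an
objective performance report for the surgeon:

1. **Force-profile segmentation.** A 1D U-Net ("T-U-Net") classifies
   every sample as ON (active tool use) or OFF (idle); post-processing
   merges noise-driven discontinuities and extracts continuous force-ON
   blocks `[start, end)`.
2. **Feature engineering.** Each force segment is summarized by 29
   hand-crafted time-series features (duration, range, spectral entropy,
   ARCH heterogeneity, spikiness, trend structure, prong correlation, …),
   with KNN-permutation and gradient-boosting importance ranking and the
   canonical four-feature dashboard subset (Duration Force, Range Force,
   Entropy, Heterogeneity).
3. **Pattern recognition.** An InceptionTime-style convolutional network
   ("FTFIT": bottleneck + parallel kernels {10, 20, 40} + max-pool branch,
   residual every third module) classifies segments by surgeon skill
   (Expert/Novice) and surgical task (Coagulation vs non-Coagulation),
   with the engineered features optionally resampled into a third input
   channel; LSTM and XGBoost baselines and a hybrid logistic head on
   learned + engineered features are included.
4. **Evaluation and reporting.** Weighted F1, macro-AUC, average
   precision, stratified 5-fold CV, two-way feature ANOVA, and a
   gauge-style surgeon-vs-expert comparison emitted as data.

Because operating-room recordings cannot be redistributed, the package
includes a seeded **synthetic recording generator** calibrated to the
published dataset statistics (56.1% Coagulation segments; Coagulation
duration 12.1 s mean, 7.2 s SD, ≈58% longer than other tasks; no
skill-dependent duration gap). All benchmarks run on this generator.

The neural networks are trained by a compact, fully deterministic engine
built into the package (im2col convolutions on BLAS, batch norm, LSTM,
Adam, early stopping) — no external deep-learning framework is required.
See `vignettes/methods.Rmd` for the models, assumptions and design
decisions.

## Worked example

```r
library(forcepsml)

# 1. a 10-minute synthetic recording with ground truth
cfg <- synth_config(recording_minutes = 10)
gen <- generate_recording(cfg, seed = 7)
gen$recording
#> <force_recording> 12000 samples at 20 Hz (600.0 s), labeled
nrow(gen$truth$segments)
#> [1] 39

# 2. features of the first force segment
seg <- with(gen$truth$segments[1, ], {
  idx <- (start_idx + 1):end_idx
  forcepsml:::new_force_segment(
    cbind(gen$recording$left_force_n[idx],
          gen$recording$right_force_n[idx]),
    task, skill, surgeon_id)
})
fv <- extract_features(seg)
round(unlist(fv[subset1()]), 3)
#>  Duration Force     Range Force         Entropy   Heterogeneity
#>           8.300           1.598           0.394           0.858

# 3. generator calibration against the published duration statistics
cs <- calibration_statistics(seed = 1)
round(unlist(cs), 2)
#> coag_mean_s   coag_sd_s  task_gap_pct  skill_gap_pct
#>       12.10        7.24         59.88           0.11

# 4. desk-scale segmentation benchmark (~6 min on one CPU)
bench <- benchmark_segmentation(n_windows = 400, seed = 7)
round(bench$weighted_f1, 3)
#> [1] 0.98
```

The numbers mean: the first extracted segment lasts 8.3 s with a 1.6 N
force range; generated Coagulation durations average 12.1 s (SD 7.2 s),
~60% longer than the other tasks, while Expert and Novice durations
differ by < 1%; and the T-U-Net recovers the ON/OFF mask of held-out
synthetic windows with a point-wise weighted F1 of 0.98.

A YAML-driven command-line wrapper for the full pipeline
(simulate → segment → featurize → train → evaluate → report) ships at
`inst/cli/forcepsml-cli.R`.

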