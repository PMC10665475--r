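# respfusion

Respiratory-rate monitoring inside a moving car, for people building
unobtrusive in-vehicle health monitoring: the package detects
breathing events in multichannel cabin recordings by fusing four
redundant sensors — a piezoelectric pressure sensor in the seat belt, a
seat-belt accelerometer, and two video traces extracted from fixed
regions of interest (belt and chest) — with a seat-mounted accelerometer
serving as a noise-only reference and a chest belt as ground truth.

Three pieces make up the method:

1. **Reference-channel spectral denoising.** Both accelerometers are
   band-passed to the respiration band (0.1–0.7 Hz) and collapsed to
   one trace each by PCA over their three axes. Each frequency bin of
   the seat-belt spectrum X₁ is attenuated by how loudly the noise-only
   seat spectrum X₂ expresses that bin:

       SF(k) = exp(−|X₂(k)| / μ(|X₁|)),   X_supp(k) = SF(k) · X₁(k)

   followed by the inverse transform. On full recordings the factor is
   applied per Hann-tapered 20-s segment with overlap-add (see the
   methods vignette for why the single-transform form degenerates on
   long narrowband records).

2. **Snippet classification by CNN fusion.** All channels are resampled
   to 200 Hz, median-filtered, normalized to [−1, 1] and cut into
   201-sample windows (train overlap 190, test overlap 200). A window is
   positive when a chest-belt breathing peak falls within 0.25 s of its
   center. Four strategies share one branch type (conv 4×20 → ReLU →
   dropout 0.5 → max-pool → sigmoid dense): **early** fusion (one branch
   over all channels), **signal-based late** (one branch per signal),
   **sensor-based late** (two branches per signal), and **hybrid** (2-of-3
   majority vote over the other three). The training engine (Adam,
   class-weighted cross-entropy, fully seeded) is self-contained.

3. **Leave-one-subject-out evaluation.** Per (subject, scenario) cell
   the score is P = 100·(PPV + S)/2 with PPV = TP/(TP+FP) and
   S = TP/(TP+FN); scenario means and their average Mean_P summarize a
   strategy, and the best Mean_P is restated as the portion of driving
   time usable for respiratory-rate measurement.

A synthetic study generator (quasi-periodic breathing with exact
ground-truth peaks, resonance-dominated vehicle noise shared between the
two accelerometers, lagged video traces, native 100 Hz / 10 fps rates)
makes the entire pipeline runnable and testable without any recordings.

## Worked example

Simulate a small city-driving study, preprocess, hold out one subject,
train the signal-based late fusion, and score the held-out subject:

```r
library(respfusion)

study <- simulate_study(3, scenarios = "city", duration_s = 120,
                        master_seed = 7)
cfg   <- pipeline_config(epochs = 3)
recs  <- lapply(study, function(e) preprocess_recording(e$recording, cfg))

fold  <- split_loso(recs, "s01", cfg)
fold$train
#> <snippet_set: 4328 windows x 4 channels x 201 samples; 588 positive>

model <- train_fusion(build_model(fusion_spec("signal_late", config = cfg),
                                  cfg$snippet_len), fold$train, cfg)
model
#> <fusion_model signal_late: 4 branch(es) over [piezo, acc, video_belt,
#>  video_chest], 1057 parameters, trained>

pred <- predict(model, fold$test)
performance(confusion(pred$Y, fold$test$labels))
#> P = 83.27% (PPV = 0.704, S = 0.961; TP=3203 TN=19123 FP=1344 FN=130)
```

Read: of subject s01's 23,800 one-second test windows, 96% of true
breathing-event windows were found (S), 70% of positive calls were
right (PPV), giving P ≈ 83 — far above the ≈50 a trivial predictor
scores on this metric. `run_experiment()` loops this over every fold,
scenario, strategy and signal subset and returns a tidy table;
`aggregate_scenarios()` and `usable_time_report()` summarize it.

A thin command-line front end over the same functions is installed at
`inst/cli/respfusion.R` (subcommands `simulate`, `preprocess`,
`video2trace`, `train`, `evaluate`).

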