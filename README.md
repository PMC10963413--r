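# workloadr

Multimodal assessment of mental workload from brain, heart, and eye signals.

Operators of demanding systems — pilots, surgeons, controllers — perform best
inside a band of cognitive demand: overload and under-stimulation both degrade
performance. Longitudinal studies probe this by having participants repeat a
battery of cognitive tasks (working memory, vigilance, risk assessment,
shifting attention, situation awareness, inhibitory control) over several
weekly sessions at two difficulty levels, while six biomedical modalities are
recorded simultaneously: prefrontal fNIRS, whole-head EEG, ECG, ear-clip PPG,
EOG, and remote eye-tracking. `workloadr` implements that entire measurement
pipeline as a tested R package, driven by a synthetic-data generator with
known injected effects so every stage can be validated without access to any
human recordings.

The package provides, per modality:

* **fNIRS** — low-pass FIR filtering (Hamming, order 20, 0.1 Hz cutoff),
  sliding-window motion-artifact rejection (SMAR), and the modified
  Beer-Lambert law. For ΔOD~λ~(t) = −log₁₀(I~λ~(t)/I̅~λ,baseline~),

      [ΔHbO, ΔHbR]ᵀ = (E · diag(L))⁻¹ [ΔOD₇₃₀, ΔOD₈₅₀]ᵀ,  L_λ = d · DPF_λ

  with Oxy = HbO − HbR and HbT = HbO + HbR, then five block statistics
  (mean, slope, peak, time-to-peak, sum) per optode and chromophore —
  16 × 4 × 5 = 320 measures.
* **EEG** — 60 Hz Butterworth notch (order 8), 1–59 Hz band-pass (order 7),
  EOG artifact removal (regression or component-correlation), simplified
  artifact subspace reconstruction, moving-window Welch band powers
  (delta/theta/alpha/beta/gamma) and the ratio indices
  engagement = β/(α+θ), θ/α, θ/β, (θ+α)/(β+α) — 32 × 9 = 288 measures.
* **Cardiac** — Pan-Tompkins-style R-peak detection with deterministic
  correction, PPG pulse detection with false-peak rejection and morphology,
  SDNN, RMSSD, and Welch tachogram spectra (LF 0.04–0.15 Hz, HF 0.15–0.4 Hz,
  absolute/relative, LF/HF) — 8 ECG and 10 PPG measures.
* **Ocular** — adaptive-acceleration saccade detection from calibrated
  two-channel EOG (3 measures), I-DT fixation detection from gaze, and seven
  gaze/pupil block features.
* **Statistics** — per-measure linear mixed models (session × condition fixed
  effects, subject random intercept, REML, heterogeneous diagonal residual
  variances), partial η² = F·df₁/(F·df₁ + df₂), Benjamini-Hochberg FDR across
  optode/electrode families, and a bootstrap-repeated PCA partition of
  explained variance across modalities.

## Worked example

```r
library(workloadr)
library(dplyr)

# one subject, first working-memory session, all six modalities
study <- wl_simulate_study(1, seed = 1, tasks = "WorkingMemory")
study$truth <- filter(study$truth, task_session == 1)
ft <- wl_feature_table(study, seed = 1)

ft |> group_by(modality) |> summarise(n_measures = n_distinct(measure_name))
#> # A tibble: 7 × 2
#>   modality    n_measures
#>   <chr>            <int>
#> 1 ecg                  8
#> 2 eeg                288
#> 3 eog                  3
#> 4 eye                  7
#> 5 fnirs              320
#> 6 performance          2
#> 7 ppg                 10
```

The counts are the bookkeeping invariant of the feature layer: 320 fNIRS, 288
EEG, 8 ECG, 10 PPG, and 3 EOG measures per block, plus the seven eye-tracking
features and the behavioural measures.

With several subjects, the statistical layer fits one mixed model per
measure and partitions variance across modalities:

```r
study <- wl_simulate_study(20, seed = 2, tasks = "WorkingMemory")
beh   <- simulate_behavior(study$truth, seed = 2)
fit   <- fit_lmm(beh, "perf.reaction_time")
tidy(fit)
#> # A tibble: 3 × 7
#>   measure_name       factor           F df_num df_den        p partial_eta2
#> 1 perf.reaction_time session     22.4        2    335 7.48e-10      0.118
#> 2 perf.reaction_time condition   83.0        1    335 7.55e-18      0.199
#> 3 perf.reaction_time interaction  0.565      2    335 5.69e- 1      0.00336
```

Reaction time shows the injected learning effect (faster over sessions) and
workload effect (slower under the hard condition); the partial η² column is
the effect size reported alongside each F test.

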