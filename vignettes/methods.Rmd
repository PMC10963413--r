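---
title: "Methods: six-modality workload assessment with workloadr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: six-modality workload assessment with workloadr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(workloadr)
```

`workloadr` implements a complete multimodal mental-workload measurement
pipeline: a synthetic generator for six biomedical modalities under a
multi-session, two-difficulty task protocol; per-modality signal-processing
chains; and the block-level statistical layer (mixed models, FDR control,
effect sizes, PCA variance partition). This vignette records the models, the
parameter choices that matter, and the design decisions taken where the
published processing conventions leave latitude.

## The study design being emulated

The protocol spans four weekly sessions. Each of six cognitive tasks is
performed in exactly three sessions per subject: sessions 1–3 each hold four
of the six tasks and the final session holds all six, so a subject
contributes 18 task-sessions. `generate_protocol()` rotates the
task-to-skipped-session assignment across subjects (tasks are paired; the
pair skipping each early session cycles with the subject index), which keeps
the per-task appearance counts in sessions 1–3 balanced to within one
subject for any cohort size, while within-session task order is shuffled
pseudo-randomly.

Within a task run, blocks alternate easy and hard difficulty. Most tasks
present three blocks per condition; the vigilance run is a single contiguous
sweep split into eight segments (first four low, last four high workload),
and the situation-awareness task presents two blocks per condition. A 30 s
rest baseline precedes the first block. Inter-block gaps are not fixed by
the protocol description, so they are configurable; the default of 15 s
yields run lengths of roughly five to seven minutes, matching the stated
per-task duration. Block durations (30–40 s by task) are likewise defaults
chosen to land in that range.

## The synthetic generator

The generator's role is to produce recordings whose ground truth is known
exactly, so that every downstream stage can be validated by recovery rather
than by eyeballing. Injected effects are configured by `wl_effects()`:
session (learning) effects shift parameters linearly per repeat of a task,
condition (workload) effects shift hard blocks. Defaults are moderate,
physiologically plausible contrasts: +0.4 µM haemodynamic amplitude and
−20 % alpha power under load, −30 ms RR interval, +0.3 mm pupil diameter,
+150 ms reaction time, reduced accuracy; learning shortens reaction times by
10 % per session and lengthens RR by 20 ms. `wl_effects(null = TRUE)` zeroes
every contrast for calibration studies.

Per modality:

* **fNIRS** (16 optodes, 2 Hz, 730/850 nm): HbO responses are block boxcars
  convolved with a canonical double-gamma impulse response (peak 6 s,
  undershoot 16 s, undershoot ratio 1/6), scaled so the *step response*
  plateaus at the injected amplitude — normalising by the impulse-response
  area instead would overshoot the plateau by ~14 % during the initial lobe.
  HbR is −⅓·HbO. Concentrations are pushed through the forward modified
  Beer-Lambert model to raw intensities, so the generator and the inverse
  share the same extinction constants and the round trip is testable.
  Physiological noise is added as 0.1 Hz (Mayer wave) and 0.25 Hz
  (respiratory) optical-density modulations plus multiplicative white noise.
* **EEG** (32 channels, 500 Hz): a sum over the five classical bands of
  band-limited Gaussian noise whose variance follows the block's band scale,
  plus 1/f background, a 60 Hz line component (default 20 µV, a level
  typical of unshielded dry-electrode recordings and strong enough to stand
  tens of dB above the background PSD), and stereotyped blink deflections on
  frontal channels when blink times are supplied.
* **Cardiac**: beat times are generated iteratively from an RR function —
  block-wise mean RR modulated by 0.1 Hz and 0.25 Hz sinusoids whose
  variance split follows the block's LF/HF ratio, plus white jitter. ECG is
  a sum-of-Gaussians PQRST template train; PPG is a smooth raised-sine
  pulse train delayed 250 ms.
* **Ocular** (EOG at 500 Hz, gaze/pupil at 60 Hz): a fixation–saccade
  alternation with exponential fixation hold times at the block's saccade
  rate. Saccades follow the main sequence
  $V_{peak} = V_{max}(1 - e^{-A/A_0})$ ($V_{max} = 500$ °/s, $A_0 = 15$°)
  with minimum-jerk displacement profiles, so duration is
  $1.875\,A/V_{peak}$. EOG channels are the eye position scaled by the
  calibration constant (10 µV/°, shared by generator and detector, closing
  the units loop without a real calibration). Blinks appear as spikes on
  vertical EOG and NaN dropouts in the pupil trace.

What the generator does *not* emulate: realistic ECG morphology variation,
EEG source geometry and volume conduction, smooth pursuit, gaze-dependent
pupil foreshortening, slow sensor drift, or motion artifacts coupled across
modalities. Passing recovery tests therefore demonstrates the correctness of
the processing chains under the stated signal models, not robustness to
every artifact class found in real recordings.

## Signal-processing chains

**fNIRS.** Intensity → FIR low-pass (Hamming window, order 20, cutoff
0.1 Hz, group-delay compensated, coefficients normalised to exact unit DC
gain) → SMAR → MBLL. SMAR computes a sliding-window SD profile per optode
(window 4 s) and masks windows exceeding 3× the running median SD, plus any
saturated samples; masked samples are excluded from baselines and block
statistics rather than interpolated. The MBLL baseline is the 30 s pre-task
rest of the session by default (per-block baselining is available via the
`baseline` argument). Extinction coefficients default to a standard adult
table at 730/850 nm, DPF 6.0, separation 2.5 cm; all recovery tests are
forward/inverse, so these constants cancel and their absolute accuracy is
immaterial to the package's claims. The block "peak" is the signed maximum
and time-to-peak is referenced to block onset.

**EEG.** 60 Hz notch (Butterworth order 8) → 1–59 Hz band-pass (order 7) →
optional EOG artifact removal → optional simplified ASR → Welch band powers.
All IIR filtering is zero-phase (forward–backward), chosen to avoid phase
distortion of block-locked features; this doubles the effective order.
Numerically, the order-8 band-stop is applied as two cascaded order-4
sections and the band-pass as cascaded order-7 high- and low-pass biquad
cascades (poles bilinear-transformed individually): expanding either design
into a single transfer function is unstable in double precision at 500 Hz.
The gamma band is capped at 59 Hz, the band-pass edge. Welch band powers use
a 2 s moving window, 1 s hop, Hamming sub-segments of half the window with
50 % overlap; block features are means of window values fully inside the
block. EOG removal defaults to channel-wise regression (appropriate for
short recordings); the component route zeroes principal components whose
absolute correlation with either EOG channel exceeds 0.7 before
reconstruction. ASR is disabled by default and reconstructs directions
exceeding `cutoff_sd` (20) calibration SDs within 1 s windows.

**Cardiac.** R-peaks: band-pass 5–15 Hz → derivative → squaring → 150 ms
integration → adaptive threshold with 250 ms refractory, apex refined on
the band-passed signal. The published pipelines' manual editing step is
replaced by a deterministic rule — intervals deviating more than 30 % from
the running median RR are deleted or flagged — so runs are reproducible.
Pulses: order-7 0.1–10 Hz band-pass, local maxima above half the
upper-decile prominence, and a minimum-distance rule of 0.6× the running
median inter-pulse interval, which also rejects dicrotic notches. Spectral
HRV interpolates the tachogram to 4 Hz (cubic spline), detrends, and
integrates a Welch PSD over 0.04–0.15 and 0.15–0.40 Hz. "Relative" power is
normalised units, band/(LF+HF) — hence `lf_rel + hf_rel = 1`, consistent
with identical F statistics for the two relative-power measures in
repeated-measures analyses. Blocks shorter than 120 s carry a reliability
flag on spectral metrics but are still emitted.

**Ocular.** The EOG saccade detector smooths calibrated position with a
Savitzky–Golay filter (20 ms window), differentiates by central
differences, and thresholds the acceleration of radial velocity at
k = 3.4 times a running noise scale. That scale is a rolling MAD rather
than a rolling SD: the saccadic transients themselves would inflate a plain
SD and suppress detections exactly when saccades are frequent. An event is
an opposite-sign acceleration peak pair within 100 ms; events closer than
50 ms are merged (at 80 ms, distinct saccades in dense scanpaths begin to
merge and recall drops measurably). Amplitude is the 2-D displacement from
onset to offset. Fixations use I-DT on gaze (dispersion = x-range +
y-range ≤ 1°, minimum 100 ms); inter-fixation shifts are emitted as
gaze-source saccades, keeping fixation + saccade + unclassified time a
partition of the interval. Pupil blinks (NaN runs ≤ 500 ms) are linearly
interpolated; longer gaps are excluded from means. The default eye-tracking
feature set is the seven listed workload correlates (pupil diameter,
saccade velocity and length, fixation count, duration, rate, and
fixation/saccade time ratio).

## Statistical layer

Each measure is modelled with fixed effects of task session (categorical),
condition, and their interaction, and a random intercept per subject,
estimated by REML. The "diagonal covariance" convention of point-and-click
mixed-model software is read as heterogeneous residual variances across the
six session × condition cells; the default engine fits this with
`nlme::lme` + `varIdent` and reports marginal (Type III, sum-to-zero
contrast) F tests. No installed machinery provides Satterthwaite degrees of
freedom for that heterogeneous fit, so fractional denominator df are
available through the alternative `engine = "lmer"` (lmerTest,
homogeneous residuals); on balanced synthetic data the two engines agree
closely, and in the degenerate zero-subject-variance limit both reproduce
the fixed-effects ANOVA F. Non-convergence of the heterogeneous fit falls
back to the homogeneous model and flags the result. Partial
η² = F·df₁/(F·df₁ + df₂) is computed for every emitted test.

FDR control follows the Benjamini–Hochberg step-up rule, applied
independently within channel families — all 16 optodes of one
chromophore-statistic, or all 32 electrodes of one band or ratio, per fixed
factor — so the correction runs across optodes and electrodes within each
processed data type. Other modalities, with a handful of measures each, are
assessed at the raw α = 0.05.

The PCA variance partition z-scores features, eigendecomposes the
correlation matrix, and retains components with eigenvalue > 1. Because PCA
itself is deterministic, "repeated runs with different starting seeds" is
interpreted as bootstrap resampling of observations per repeat — this
produces the non-integer mean component counts and stabilised shares that
repetition implies. A modality's share is the eigenvalue-weighted sum of its
features' squared loadings over retained components, normalised across
modalities (so shares sum to 100 by construction); means over 30 repeats are
reported with per-repeat detail retained. Missing cells are mean-imputed
before scaling; zero-variance features are dropped with a warning.

Report-row selection mirrors the summary-table convention: at most five rows
per modality, fNIRS/EEG rows must be FDR-significant, ordered by descending
partial η², with at least one row per significant factor.

## Numerical choices and degenerate inputs

* Filters: all zero-phase; high-order IIR designs applied as biquad or
  half-order cascades (see above); FIR coefficients renormalised to unit DC
  gain so constant signals pass exactly.
* Welch integration is rectangular over half-open bands `[lo, hi)`;
  windows with zero denominators in ratio indices are emitted missing.
* Block features require ≥ 4 unmasked samples, beat metrics ≥ 3 beats,
  spectra ≥ 8 beats; below these, missing values are emitted rather than
  guesses.
* Flat ECG, empty PPG, and pure-noise EOG produce empty event series with
  warnings, not errors.
* All simulators draw from deterministic child seeds of one user seed;
  fixed seeds give bit-identical recordings and hash-identical pipeline
  outputs.

## Problem sizes used by the test-suite

The suite validates the statistical layer at 20 subjects × 6 blocks with
100 null replicates (type-I calibration) and 50 replicates for power; FDR
behaviour at 100 measures × 1000 seeds; recovery properties on single
recordings of 4–6 minutes; and the end-to-end determinism check on a
two-subject, one-task dataset with the fNIRS and cardiac modalities. These
sizes keep the full suite to a few minutes while leaving every estimate's
Monte-Carlo error well inside the asserted tolerances.

## Limitations

Recovery rates and calibration results are statements about the generator's
signal models. Real dry-electrode EEG, ear-clip PPG, and remote eye-tracking
carry artifact classes (electrode pops, perfusion changes, track losses)
that the chains here handle only via their generic masking rules. The
heterogeneous-variance engine reports containment rather than Satterthwaite
df; with hundreds of residual degrees of freedom the practical difference
is negligible, but small-sample df will differ from software that
implements Satterthwaite on the heterogeneous model. The PCA bootstrap
interpretation is one reasonable reading of "repeated with different
seeds"; an alternative (random eigensolver initialisation) would leave
shares unchanged and component counts integer.
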