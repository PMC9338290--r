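---
title: "Methods: cuffless blood pressure estimation from multiparametric wearable signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cuffless blood pressure estimation from multiparametric wearable signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuffless)
```

## The problem

Cuff-based blood pressure (BP) monitoring at home is error-prone and
burdensome; cuffless approaches built on pulse-wave timing (pulse transit
time, pulse arrival time) need per-subject cuff calibration and are
confounded by arterial stiffness, age and body habitus. `cuffless`
implements an alternative: estimate systolic and diastolic BP (SBP/DBP,
mmHg) from *centrally measured* signals — two ECG channels, a
phonocardiogram (PCG) recorded near the cardiac apex, and two thoracic
impedance channels — combined with demographics (age, sex, height,
weight), using ensembles of regression trees and no calibration step.

The physiological rationale: the timing of the second heart sound S2
relative to the ECG R peak reflects systolic time intervals (electro-
mechanical systole shortens as contractility and pressure rise), heart
sound amplitudes reflect valve closure energetics, and thoracic impedance
carries respiration rate and tidal-volume surrogates that co-vary with
hemodynamic state.

## The pipeline

1. **Quality screening** (`assess_quality`). Each second of each channel
   is acceptable or not: amplitude saturation (a run of ≥ 50 samples at
   the channel rail), flatline (variance below a floor), movement (mean
   activity-channel amplitude above a threshold), and beat-consistency on
   ECG (an RR interval outside [0.3, 2] s marks the seconds it covers).
   These concrete criteria are this package's own choices — the data-
   preparation rule they implement ("remove movement-corrupted segments")
   names no algorithm. Bad data is excluded, never repaired.
2. **Window association** (`associate_window`). For each time-stamped
   reference observation, the *latest* fully acceptable 60-s window inside
   the 300-s lookback preceding the timestamp is paired with it; if none
   exists the observation is rejected with a reason. Sources describing
   this protocol disagree between "preceding" and "centered on the
   measurement" windows; both are implemented (`window$mode`), and
   *preceding* is the default because the data-preparation rule is the
   authoritative statement of how the dataset was assembled.
3. **Feature extraction** (`build_feature_vector`). R peaks via a
   Pan-Tompkins-style detector (band-pass 5–25 Hz, differentiate, square,
   150-ms integration, chunk-local adaptive threshold, 250-ms refractory;
   locations refined on the zero-phase band-passed trace). Beat-aligned
   ensemble averages over the window (outlier beats with correlation to
   the pointwise mean < 0.5 are dropped; ≥ 5 survivors required). On the
   PCG ensemble, S1 is the strongest envelope peak in (0, 0.25 RR] after
   R and S2 in (0.25 RR, 0.6 RR] (Hilbert envelope; ±40 ms RMS windows).
   Band RMS features use 20–50 / 50–100 / 100–240 Hz defaults; the upper
   edge stops below the 250-Hz Nyquist of the 500-Hz PCG. Respiration
   rate is the dominant periodogram peak in 0.07–1 Hz (parabolically
   interpolated, so a 60-s window resolves well under 0.5 breaths/min);
   relative tidal volume is the mean respiratory peak-to-trough excursion
   (2√2 × band-limited RMS, exact for a sinusoid) over mean impedance.
   The band edges and the tidal-volume definition are provisional
   in-package definitions: the feature names are fixed by the study's
   selected-feature lists, but their exact definitions are not public.
4. **Reference rules** (`reconcile_observers`, `entry_bp`,
   `classify_jnc7`). Two observers read one sphygmomanometer through a
   Y-connector to the nearest 2 mmHg; pairs differing by more than
   4 mmHg are retaken, otherwise the unrounded mean is the reference.
   Entry BP is the mean of three seated readings and fixes the JNC 7
   class (normal / prehypertension / stage 1 / stage 2; "normal" needs
   both pressures strictly below 120/80, the hypertensive classes use
   or-logic, shared boundary values resolve to the higher class).
   Sequential devices (a wrist cuff) are scored against the mean of the
   two references bracketing the reading (`make_pairs`,
   mode `"adjacent_mean"`).
5. **Modeling** (`split_dataset`, `select_features`, `train_models`).
   Observations are split 80/20 by a seeded permutation
   (train = ⌊0.8 n⌋; a subject-level split mode exists for leakage
   experiments but the observation-level split matches the study design).
   Feature selection fits a seeded random forest, normalizes impurity
   importances to sum to 1, and keeps features above 2% relative
   importance — demographics compete on equal terms. Each BP target is
   then fit by a fixed, seeded, heterogeneous ensemble (random forest +
   gradient-boosted trees + bagged trees, averaged). The study obtained
   its ensembles from a time-budgeted AutoML search; a fixed seeded
   specification replaces that search deliberately — reproducibility over
   fidelity to a non-deterministic procedure — so the original ensemble
   sizes (five systolic, eight diastolic members) are *not* reproduced.
   The baseline uses demographics only, with the same hyperparameters.
6. **Evaluation** (`stratified_report`, `bootstrap_rmse_comparison`,
   `bootstrap_mad_ci`). MAD = Σ|pᵢ−yᵢ|/n, MAPD = Σ100|pᵢ−yᵢ|/yᵢ/n,
   RMSE = √(Σ(pᵢ−yᵢ)²/n), reported per condition stratum × split ×
   target, with Bland-Altman statistics (mean difference ± 1.96 SD) on
   the test split. The model-vs-baseline comparison draws 10,000
   bootstrap resamples of the test set (each of full test size, with
   replacement), computes both RMSEs *on the same indices* per resample
   — the paired design is the variance-correct reading of the
   RMSE-difference method — and declares superiority when the upper 95%
   percentile bound of the difference is below 0 mmHg; the p-value is the
   fraction of resamples with difference ≥ 0, floored at 1/10,000.
   Percentile intervals are used throughout (no BCa): only a "95% CI" is
   specified, and percentile intervals are the simplest exchangeable
   choice. MAD uncertainty uses 1,000 resamples.

## The synthetic-data generator

No public dataset exists for this device class, so the package ships a
generator (`generate_cohort`, `synthesize_recording`,
`simulate_observers`) whose defaults *are* the study conditions: a cohort
stratified 20/37/26/18% across the four JNC 7 classes (the printed
percentages sum to 101%; counts are ⌊fraction·n⌋ with the residual to the
largest class, giving 24/44/31/21 at n = 120), ages 18–83, both sexes, a
four-block protocol (static, warm stimulus, cold pressor + walk, rest)
with three consecutive readings per block at ≥ 60-s spacing, observers
with 2-mmHg-grid rounding (ties to even — the protocol says only
"nearest") and independent 2-mmHg noise, and a wrist-cuff column with
larger bias and noise.

Waveform morphology is invented, chosen for exactly known ground truth
rather than realism: sum-of-Gaussians ECG beats (the R-wave width is set
so the |x| > 0.1·R interval equals the planted QRS duration),
Gaussian-windowed tone bursts for S1 (35 Hz) and S2 (55 Hz), a
phase-continuous tidal sinusoid plus small cardiac ripple for impedance,
and movement epochs that drive the activity channel high while corrupting
every channel. Default sampling rates (ECG/PCG 500 Hz, impedance 50 Hz,
activity 25 Hz) are likewise invented defaults — the device's true rates
are not public — and all of this is configurable.

The signal↔BP coupling exists solely so recovery and superiority tests
have a known answer: R-to-S2 = 0.40 − 0.001·SBP s (≈ −1 ms/mmHg, the
order of magnitude of systolic-time-interval shifts), S1/S2 RMS ratio
= 1.5 + 0.01·(DBP − 80), respiration weakly coupled to SBP. With
`coupling$enabled = FALSE` the generator becomes a null model: those maps
are replaced by fixed values *and* the condition responses of heart rate
and respiration are zeroed — condition drives BP, so a condition-coupled
heart rate would otherwise remain an indirect signal-BP pathway and the
null would be false.

`simulate_feature_dataset()` is a feature-level fast path: it draws the
per-observation feature vectors directly from the same planted
hemodynamics plus measurement noise, skipping waveform rendering. The
waveform path is verified (noise-free) to recover the planted parameters
to within one sample / 0.5 breaths/min / 5%, so the fast path is the
statistically equivalent route for Monte-Carlo model-level experiments
(100 seeded end-to-end runs complete in minutes rather than hours).

What passing tests on synthetic data do *not* show: the generator has no
arrhythmia, murmurs, electrode artifacts, posture effects or real
inter-subject morphology variation, and its coupling is far cleaner than
physiology. Green tests demonstrate the *machinery* is correct — they say
nothing about accuracy on real patients, and the study's printed
accuracies (e.g. test MAD ±6.38/±5.10 mmHg) are not reproducible without
its private clinical data.

## Numerical and design notes

* Windows are half-open `[start, end)` on a 1-s mask grid; ties in
  window association cannot occur because the latest start wins.
* Observer means are kept unrounded (121 mmHg is a legal reference);
  the 2-mmHg grid applies to raw readings only. Odd raw readings warn
  but are retained — real transcription deviates.
* A missing feature is an `NA` plus a `TRUE` flag; model matrices
  median-impute flagged features and add 0/1 indicator columns, so no
  `NaN`/`Inf` ever reaches a fit silently. An observation missing more
  than a third of its signal features is dropped with a logged reason
  (one-third rather than a stricter cut so that a single dead channel —
  e.g. a flat PCG, which costs 5 of 16 signal features — degrades
  gracefully instead of discarding the observation).
* Every random operation takes an explicit seed derived from the single
  config seed; identical (config, seed) gives byte-identical evaluation
  and comparison JSON.
* Demo problem sizes: the shipped demo config runs 40 subjects × 12
  scheduled observations with full waveform synthesis (~390 usable
  observations); the acceptance Monte-Carlos use 50 seeds per arm at the
  same cohort size via the feature-level path, and bootstrap sizes follow
  the study (10,000 comparison / 1,000 MAD resamples).

## Known limitations

* The S-band edges, tidal-volume definition and quality thresholds are
  defensible defaults, not reverse-engineered truth; treat absolute
  feature values as package-defined.
* The AutoML search and hence the exact published ensembles are out of
  scope by design; only the class of model (seeded tree ensembles) is
  preserved.
* EDF export is not implemented; recordings interchange as the WFDB-style
  CSV + JSON layout.
* Windows rejected for quality are simply absent — no imputation of
  missing observations is attempted, matching the study's exclusion rule.
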