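---
title: "Beat-by-beat wavelet delineation and log-linear blood-pressure estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-by-beat wavelet delineation and log-linear blood-pressure estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewave)
```

## The problem

Cuffless blood-pressure estimation exploits the delay between the heart's
electrical activation and the arrival of the pressure pulse at the
periphery: the pulse arrival time (PAT), measured from the ECG R peak to a
landmark of the concurrent photoplethysmogram (PPG).  PAT alone does not
determine pressure — arterial elasticity varies with many factors — so this
package extracts a 32-interval feature set spanning both channels of a
concurrent ECG/PPG recording, beat by beat, and regresses the logarithm of
systolic and diastolic pressure on a selected subset.

Everything hinges on locating waveform landmarks ("fiducial points")
reliably on *continuous* recordings whose beat period drifts with heart
rate.  The package's delineators combine three ingredients:

1. **Haar wavelet decomposition.**  A five-level orthonormal Haar analysis
   (`haar_dwt()`).  Detail coefficients are scaled local slopes, so steep
   deflections (the QRS complex, the PPG pulse edges) appear as extreme
   detail coefficients: level 3 (8-sample scale at 1200 Hz) isolates the
   QRS-like edges, level 5 (32-sample scale) the slower P, T and diastolic
   waves.
2. **Modulus-maxima analysis** (`modulus_maxima()`): strict local maxima of
   the level-1 detail modulus above a relative floor mark signal
   singularities; their counts around a candidate peak certify that the
   surrounding low-amplitude waves are inside the analysis window.
3. **Adaptive windowing.**  One beat is delineated per window whose size
   tracks the running R-R (ECG) or pulse (PPG) interval plus a 25% buffer,
   re-estimated before every beat, so a window always holds exactly one
   complete cycle at any heart rate from 50 to 110 bpm.  A fixed-window
   baseline (1100 samples, `mode = "fwwt"`) is provided for comparison: it
   tiles the stream without checking beat placement and loses beats as soon
   as the rate leaves the narrow band where one beat fits one tile.

All processing happens at a working rate of 1200 Hz.  Native recordings
(200 Hz ECG, 75 Hz PPG in transmission-intensity orientation) are upsampled
by linear interpolation — factors 6 and 16 — so that five halvings still
leave at least 128 samples per window, the minimum for the modulus-maxima
analysis.

## Window validity

A window is accepted only when

* the anchor peak (R, or the PPG end-of-beat EB) is detected,
* the anchor lies within 10% of the window size of the window center, and
* more than 2 modulus-maxima points flank it on each side (ECG), or more
  than 3 before / 2 after (PPG).

Rejected windows slide forward 10 samples and retry, with a retry budget of
twice the window size over the slide step before one whole window is
skipped; this bounds the runtime on pathological input.  After a successful
beat the ECG search restarts at the current T wave, the PPG search one
tenth of a window before the current EB (the end of one pulse is the
beginning of the next).

## Delineation rules and the judgment calls behind them

The ECG rules are: `t1`/`t2` = level-3 detail extrema bracketing the QRS
(steepest upslope, then the steepest downslope *after* it — the restricted
pairing keeps a second beat in the window from splitting the bracket);
R = raw argmax between them; Q and S = amplitude minima between R and the
neighboring modulus maxima `t3`/`t4`; QRS onset/offset by a derivative
threshold; P and T = raw-amplitude maxima bracketed by the level-5 detail
extrema of the pre-onset and post-offset segments.

Four points deserve explanation because the mechanism is genuinely open:

* **QRS onset/offset.**  A derivative-threshold rule needs a slope
  estimate that is not dominated by wideband noise; the slope is taken at
  the QRS scale (9-sample moving average, central difference over ±4
  samples) and the walk runs *outward from Q and S*: it first crosses the
  steep flank and then stops at the first sample whose |slope| falls below
  `qrs_slope_frac` (default 0.05) of the window's largest slope.  The
  thresholds are relative, keeping the rule amplitude-invariant.
* **The P search region** is additionally capped at
  min(0.22 s, 35% of the implied beat period) before the QRS onset.  A
  correctly centered window *always* contains the previous beat's T wave,
  which is larger than P and otherwise captures the level-5 extrema; the
  cap is a generous clinical bound on the P-to-QRS interval.  Level-5
  coefficients whose 32-sample support overlaps the QRS are likewise
  excluded.
* **The diastolic peak (DP).**  The level-5 detail is a (negated) smoothed
  derivative, so a zero-crossing from negative to positive marks a local
  amplitude *maximum*.  Scanning left from the maximum of the
  differentiated detail (the sharpest concave-down point, i.e. the EB top),
  each peak-direction crossing within the last 40% of the window — but
  clear of EB's own support — is a candidate; since the 32-sample
  coefficient grid quantizes the crossing position, every candidate is
  refined against the raw amplitude in its support and the highest summit
  wins.  The diastolic summit dominates both the notch and valley noise.
* **The dicrotic notch (DN).**  The notch is a small bump riding the
  systolic-to-diastolic rise.  Modulus maxima between SP and DP mark its
  slopes; each candidate is climbed to its local summit and scored by
  topographic prominence over the [SP, DP] segment (height above the higher
  of the two surrounding minima).  The most prominent summit above 0.8% of
  the window range is the notch; a beat whose rise carries no such summit
  gets `dn = NA` and the eight DN-dependent features are skipped for that
  beat.  An earlier rule — "the modulus maximum nearest the SP–DP
  midpoint" — was abandoned because it answers with the midpoint's
  position, not the notch's, flattening any real variation in notch timing.

All detection decisions use only ranks of coefficients and amplitudes, so
results are invariant under amplitude scaling and DC offset of the input;
this is tested.

## Features, pairing and aggregation

Per beat, 32 durations are computed (5 ECG-only, 7 PPG-only, 20
cross-channel transit times `T_iA/T_iB/T_iN1/T_iN2` between each ECG wave
and each PPG landmark; `T_RN2` is the classical PAT).  Simultaneity is
enforced by back-tracing: each PPG beat pairs with the latest unclaimed R
peak preceding its diastolic peak.  A segment of 80000 samples (about 67 s)
follows a 10000-sample settling skip; each feature column is reduced by a
one-pass mean ± SD filter (`robust_mean()`), which removes the occasional
wild interval a detection slip produces, and requires at least 20 paired
beats.

Intervals are reported as nonnegative (later minus earlier) durations.
Inter-beat intervals (`Trr`, `Tbb`, `Taa`) run forward to the next beat and
are missing for a segment's last beat.

## The blood-pressure model

`fit_log_linear()` is ordinary least squares of `ln(BP)` on the feature
columns: the semi-log form mirrors the inverse-exponential pressure–transit
relation, guarantees positive predictions, and matches the scale of
millisecond features to a ~100 mmHg response.  Feature selection offers the
published 9-feature SBP / 14-feature DBP sets (`default_feature_sets()`), a
univariate R² screen at 0.3 (`screen_features_r2()`), and a deterministic
greedy-forward wrapper over cross-validated MAE (`wrapper_select()`).  The
wrapper accepts a feature only if it improves CV MAE by at least 1%
(configurable): CV scores fluctuate, and without a parsimony margin pure
noise enters roughly every third run.  Evaluation (`evaluate_bp()`) reports
ME, MAE and the n−1 standard deviation of errors, Bland–Altman pairs, BHS
cumulative-error percentages (grade A = 60/85/95% within 5/10/15 mmHg,
B = 50/75/90, C = 40/65/85, else D) and the AAMI criterion
(|ME| ≤ 5 and SD ≤ 8 mmHg).

## What the synthetic generator emulates — and what it does not

`synth_paired()` builds both channels on a shared beat clock: ECG beats are
five Gaussian bumps (P, Q, R, S, T) with fixed offsets; PPG beats, in
transmission-intensity orientation, are an end-of-beat peak, a systolic
trough `pat` seconds after R, and notch/diastolic bumps at fixed fractions
of the beat period.  Beat-to-beat variability is lognormal with unit mean
(default 2% SD).  Channels are synthesized at their native rates (200 and
75 Hz) and upsampled exactly as real recordings would be.  Noise is drawn
at the native rate and carried through the same interpolation — acquisition
noise is band-limited; injecting white noise at 1200 Hz would create
spectral content no physical front end produces.  The default
signal-to-noise ratio is 30 dB, a typical clean bedside recording.

Truth landmarks are the programmed bump centers — except the dicrotic
notch, whose recorded truth is the *summit of the composite waveform*: the
trough and diastolic-peak flanks drag the crest a few milliseconds from the
bump center, and the landmark of record is where the waveform actually
crests (computed once per morphology on a fine grid, in period units).

The default notch (amplitude 0.18, width 0.032 of the period, placed 0.20
of the period after the trough) is the weakest morphology still resolvable
at the 75 Hz native rate; narrower or earlier notches merge into the
systolic upstroke before the detector ever sees them.

`synth_cohort()` draws per-subject physiology (heart rate 55–100 bpm, PAT
0.15–0.33 s, notch placement 0.16–0.24 and end-of-beat placement 0.54–0.70
of the period) and generates reference pressures from a log-linear map over
`{T_RN2, Trr, Tn2b}` plus lognormal noise (`default_bp_map()`), with
intercepts anchored so the cohort centers on 128.45/77.73 mmHg with spreads
near 15/9 mmHg — the reference population the cohort emulates.  The map is
a recovery target for the pipeline, not a physiological claim.  Its third
feature is the trough-to-end-of-beat interval rather than the
trough-to-notch interval for a measurement-theoretic reason worth stating
plainly: at 75 Hz native sampling the notch summit carries a
placement-dependent localization bias of several milliseconds, and any
period-proportional feature is ~0.97-correlated with `Trr` unless its
placement fraction varies widely; together these make coefficients on a
notch feature unrecoverable to 5% by *any* detector.  The notch features
are still generated, extracted and tested — they are simply not the
coupling channel of the default map.

What the generator does **not** emulate: baseline wander, motion artifacts,
electrode noise spikes, arrhythmia, respiratory modulation, or realistic
pulse-shape families.  Passing tests therefore demonstrate the pipeline's
correctness and its noise/heart-rate robustness on idealized morphologies,
not clinical accuracy; the clinical numbers of any real deployment must be
established on real recordings.

## Numerical choices and degenerate inputs

* Orthonormal (1/√2) Haar filters, so energy is conserved and testable;
  detection uses only coefficient ranks, which any normalization preserves.
* Odd-length inputs extend by repeating the last sample at each level —
  padding with zero would fabricate an edge singularity.
* Coefficient `k` of level `l` maps to the left edge of its support,
  `(k−1)·2^l + 1`; ties in local-maximum tests keep the leftmost sample.
* The window-size estimator thresholds a 2400-sample block at 0.6 of the
  block maximum with a 200 ms refractory period; below 60 bpm such a block
  can hold a single R peak, so it doubles once before falling back to the
  fixed 1100-sample window.  Flat or empty blocks fall back immediately.
* Flat summits (the PPG end-of-beat) settle on a 25-sample moving-average
  smoothed segment so noise cannot drag the argmax across the top.
* Flat-line streams yield empty beat tables, not errors; constant windows,
  windows under 128 samples, non-positive pressures, rank-deficient
  designs, non-uniform timestamps and NaN samples are rejected with
  explicit messages.

## Problem sizes used by the test-suite experiments

Detection experiments use 60-second single-subject records per heart rate
(50–110 bpm).  The recovery experiments use 24 subjects × 80 s (noiseless
map recovery) and 16 subjects × 80 s (default-noise fit), the smallest
cohorts at which the conclusions hold with comfortable statistical margin;
the cohort-moment check uses 171 subjects (labels only, no waveforms).

## Known limitations

* At 20 dB SNR the PPG beat recall degrades to roughly 0.85–0.95 (the EB
  summit is flat and its bracket can latch onto the diastolic peak when the
  true EB sits at a window edge); the ECG side holds ≥ 95% down to 20 dB.
* QRS onset/offset are threshold conventions: their placement shifts by
  ~20 ms when the narrow Q/S flanks pass through the 200 Hz native grid,
  so the QRS-width feature is the least accurate of the 32.
* The fixed-window baseline's low-rate degradation is milder here than on
  real data, because the synthetic beat is compact relative to the beat
  period at 50 bpm.
* U waves are not detected; arrhythmia is out of scope.
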