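---
title: "Pulse-waveform analysis: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-waveform analysis: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewave)
```

## The physiological model

The peripheral pulse waveform is the superposition of a forward pressure
wave, ejected during ventricular systole, and a wave reflected from
peripheral arterial sites. In compliant arteries the reflected wave arrives
late, producing a distinct diastolic peak separated from the systolic peak
by a dicrotic notch; with arterial stiffening the reflection arrives
earlier, merges with the forward wave, and the notch blunts. The timing of
the reflection (peak-to-peak time, PPT) and its relative amplitude
(reflection index, RI) therefore index vascular state, and the full
morphology — landmark intervals, second-derivative (acceleration PPG)
curvature ratios, and the harmonic composition of the waveform — forms the
feature set this package extracts.

Smartphone acquisition adds two complications the pipeline is built around:
camera frame rates are low (~30 Hz) and unstable, so signals are resampled
onto a uniform grid before analysis; and auto-exposure smooths the systolic
peak, which motivates the *estimated* variants (ERI, EPPT, ESI) built on a
tangent-intersection reconstruction of the undistorted peak.

## Signal path and its conventions

1. **Colour conversion.** YUV frames are converted with the BT.601
   full-range matrix — the most common camera convention; the choice is a
   declared substitute since acquisition hardware varies.
2. **Channel combination.** Each frame is reduced to per-channel spatial
   means over the full frame (no region-of-interest selection), and the
   three mean series are combined with weights proportional to their
   temporal standard deviations over the whole recording. The pulse
   modulates all channels coherently while sensor noise does not, so
   SD-weighting emphasizes the channels that carry pulsatile content; with
   channels of comparable gain it also averages noise down below any single
   channel's level.
3. **Resampling and filtering.** Linear interpolation onto a uniform grid
   (default 30 Hz, the nominal frame rate), then a zero-phase Butterworth
   band-pass, default 0.5–8 Hz, order 3 — wide enough to pass the cardiac
   fundamental and its first handful of harmonics (a 1.25 Hz sinusoid is
   preserved within 0.1%) while attenuating drift below 0.1 Hz by more than
   99%. Transmissive fingertip PPG is frequently inverted, so polarity is
   auto-oriented by the sign of the filtered signal's skewness (systolic
   upstrokes become maxima); the flip is logged on the returned object.
4. **Beat segmentation.** A naive peak picker fails when the reflected
   wave is tall (it splits beats at the notch), so detection is two-stage:
   the beat period is estimated from the autocorrelation peak in the
   27–200 bpm band (taking the earliest lag within 10% of the maximum to
   avoid locking onto a period multiple), peaks are found on a low-passed
   detection trace (cutoff 1.8 cycles per estimated period) with a 0.6
   period refractory, and each peak is then refined to the raw-signal
   maximum nearby. Valleys are the minima between consecutive refined
   peaks; each BBI spans valley to valley, so it contains one full
   systolic–diastolic complex. Beats outside 0.3–2.0 s (30–200 bpm) are
   discarded as artifacts.

## Fiducial landmarks

The systolic peak (ESP) is the beat's global maximum; beats whose maximum
sits on a boundary sample are rejected as segmentation failures. The
diastolic peak is the first downward zero-crossing of the smoothed first
derivative with negative curvature after ESP. Two numerical choices matter:

- **Adaptive prominence guard.** A candidate second peak must rise above
  the intervening minimum by more than 4× the noise level (estimated as the
  SD of the Savitzky–Golay smoothing residual), with a floor of 1% of the
  systolic amplitude. Without the guard, noise wiggles on the diastolic
  tail register as reflected waves and the no-second-peak fallback
  (physiologically, the fully merged waveform of a stiff artery) could
  never fire on noisy data; a fixed threshold cannot serve both raw beats
  and denoised ensemble templates, which is why the guard tracks the
  measured noise.
- **Sub-sample refinement.** The ESP is refined by the quadratic vertex
  through the apex and the DP by linear interpolation of the derivative's
  sign change. At a PPT of 0.16 s sampled at 100 Hz, a two-sample
  discretization error is already 12%, so peak-to-peak timings use the
  fractional positions.

When no second peak survives the guard, the fallback landmarks follow the
merged-waveform convention: DP is the minimum of the second derivative
between ESP and RV, and the inflection point is designated as the notch;
such beats raise the sample's IPP percentage. The IP definition ("last
positive-to-negative first-derivative transition before the second peak")
describes a local maximum rather than a classical inflection; it is
implemented verbatim, which on a clean two-peak beat places IP at the apex
of the reflected wave — the vertex the A2 triangle needs.

The acceleration-PPG points A–H are earliest-index argmax/argmin of the
second derivative over their windows, located in dependency order (F before
E and H, H before G). "Between X and Y" is read inclusively: with a sharp
systolic apex the post-ESP curvature minimum can sit on the sample adjacent
to ESP, and an exclusive window for E would be empty on every beat. C and D
are located when their window is non-degenerate but no feature uses them —
they are unreliable in noisy signals, which is also why the aging index
uses the modified form AI = B/A − E/A on signed ratios.

Amplitudes are measured above the linear baseline joining the two valleys,
with each anchor taken as the median of ±3 samples around the valley: the
valley index is an argmin and therefore sits systematically low under
noise, which would otherwise inflate every height.

## Feature conventions

- **Tangent-intersection peak estimate.** The undistorted systolic peak is
  reconstructed as the intersection of the tangent at the maximal-upstroke
  point with the tangent at the maximal-downslope point of the systolic
  decay. The construction is isolated in `estimate_esp()` so an alternative
  estimator can be substituted.
- **Areas.** A1 is the shoelace area of the polygon (LV, ESP, DN, DN-base),
  where DN-base is the notch's foot on the LV–RV baseline — the only
  geometrically sensible closure of the polygon; A2 is the triangle
  (IP, DN, RV).
- **Spectral features.** The PSD is a Hann-window Welch estimate (10 s
  segments, 50% overlap, one-sided density scaling validated against
  Parseval). Harmonic peaks are located near multiples of the cardiac
  fundamental; S_i integrates the PSD between the midpoints flanking the
  i-th peak, the first band starting at the 0–1 midpoint. rPSD normalizes
  by ΣS₁…₆ — S₀ reflects mean signal energy, not contour, and harmonics
  beyond the sixth are negligible. NHA is the harmonic-area fraction above
  the fundamental, a declared surrogate. The Fourier weights V₀…V₆ come
  from a least-squares sinusoid fit to the length-normalized median
  template beat; note that after band-pass detrending V₀ is near zero by
  construction, so it carries little information on this path (the
  parametric cohort generator gives it independent variation).
- **Normalization.** Duration-type features are multiplied by HR/75
  (mapping each beat to the 0.8 s reference period); the path-length
  intervals PPT and EPPT are additionally scaled by 170/height. The
  stiffness indices are then recomputed at the reference height
  (SI = 1.70 m / PPT). The convention is multiplicative and idempotent at
  the reference point (75 bpm, 170 cm); normalization factors are recorded
  as attributes.
- **Aggregation.** The per-feature median across accepted beats represents
  the sample; a record is incomplete if fewer than 5 beats survive or a
  core feature is present in under half of them (the "partial feature
  loss" path of the sample-filtering report).

## Signal quality

The SQI multiplies two consistency measures: the mean Pearson correlation
between each length-normalized beat and the pointwise-median template, and
a rhythm factor max(0, 1 − 2·cv) of the beat durations. The second factor
exists because valley-to-peak segmentation forces even pseudo-beats cut
from pure noise into a common arch shape — bare template correlation floors
near 0.55 and a 0.5 gate would never fire; garbage recordings betray
themselves by wildly inconsistent beat durations. On generated recordings
the combined score separates cleanly: ≥0.8 at 25 dB SNR, ~0.5 at 5 dB, and
≤0.4 at −5 dB, so the conventional 0.5 gate discards noise-dominated
records.

## Statistical layer

Repeated recordings are nested within participants while psychological
scores are measured once per participant, so two complementary inference
modes are provided: participant-level aggregation (median per participant,
then OLS) and cluster-robust CR1 standard errors on all rows with a t(G−2)
reference. The CR1/t(G−2) combination over-rejects when the number of
clusters is small; its calibration is Monte-Carlo-verified at the scale the
package targets (~90 participants), where the empirical type-I rate stays
within binomial bounds of the nominal 5%.

Feature selection eliminates within-domain collinearity sequentially —
the worst-offending pair above |r| = 0.5 is found and its member with the
larger mean absolute correlation to the remaining features is dropped
(ties broken by column order) — then retains the two features per domain
most correlated with the outcome block. Outcome-block relevance is the
declared "top" criterion; a variance-based ranking can be substituted.
Blood pressure covariates pass through, giving 2×3 + 1 = 7 features.

The random-forest evaluation mirrors common regression defaults: 100
trees, variance splitting, nodes grown to purity, all features considered
per split, bootstrap resampling, and mean-decrease-in-impurity importances.
Folds are participant-exclusive: all rows of a participant land in exactly
one test fold, eliminating within-person leakage. One master seed fans out
per-fold seeds. Bland–Altman agreement reports bias and bias ± 1.96·SD of
the paired differences (sample SD).

## The synthetic-data generator

Each beat is a systolic Gaussian plus a reflected Gaussian delayed by
`reflection_lag` (programming PPT) and scaled by `reflection_ratio`
(programming RI), superposed on a small beat-locked cosine baseline wave,
with sinusoidal drift and white Gaussian noise at a stated SNR. The cosine
component (8% of systolic amplitude by default) exists because a bare
Gaussian pair decays to a flat line between beats, leaving the inter-beat
valley position undefined — real blood-volume pulses never flatten. The
defaults describe a resting young adult under smartphone acquisition:
0.8 s period (75 bpm), 30 Hz sampling, reflection ratio 0.5 at 0.25 s lag,
0.1 Hz drift, 25 dB SNR.

Ground truth is measured on a dense (1 kHz) noise-free prototype: with
overlapping Gaussians the realized peak positions differ by a few percent
from the raw lag parameter, and the manifest records the realized geometry.
Parameter-recovery checks compare the extractor against the manifest on the
peak-aligned ensemble-averaged beat (`ensemble_beat()`): per-beat estimates
suffer a detection-selection bias at threshold-grade reflected waves
(beats are only scored as two-peaked when noise happens to enhance the
bump), and ensemble averaging is the field-standard remedy. Per-sample
records still use per-beat medians.

Cohorts draw per-participant latent waveform parameters (resting HR,
reflection morphology, stature, blood pressure) and link psychological
scores to *participant-mean* features — the instruments are administered
once per participant — with declared slopes, noise, clipping to each
instrument's range (SWLS 5–35, SVS 7–49, PANAS subscales 10–50, PHQ-9 0–27,
GAD-7 0–21, SAM 1–9), and integer rounding. Two feature paths exist:
`mode = "signal"` synthesizes a waveform per sample and runs the full
extraction pipeline; `mode = "parametric"` draws features directly from the
same latent model and is used for Monte-Carlo studies of the statistics
layer, where waveform synthesis adds cost but no information.

## What the tests do and do not show

The test suite runs entirely on generated data: closed-form oracles
(Parseval power splits, shoelace areas, linear-interpolation bounds,
Bland–Altman identities), exhaustive-scan equivalence for every extremum
landmark, and parameter recovery across a grid of reflection lags
(0.18–0.35 s) and ratios (0.2–0.8) at 20 dB SNR — 1000-beat oracle sweeps,
a 250-cell recovery grid, 200-cohort null calibration at the 91-participant
scale, and 50-cohort leakage checks, sized to run in about a minute while
keeping Monte-Carlo error small. The two-Gaussian beat model exposes every
landmark the feature set needs but does not emulate motion artifact,
ambient-light steps, saturation, or HR variability within a recording;
passing these suites shows the machinery is correct and calibrated under
the stated morphology, not that feature estimates are accurate on arbitrary
real-world recordings.

## Known limitations

- The SQI is a declared surrogate; only its 0.5 gate is fixed by
  convention. Any monotone quality score could replace it behind the same
  interface.
- The tangent-intersection peak estimate, the NHA surrogate, and the
  multiplicative HR/stature normalization are declared conventions,
  each isolated behind one function for substitution.
- V₀ is nearly constant after band-pass detrending (see above).
- At 30 Hz sampling, second-derivative landmarks on sharp systolic
  upstrokes sit within one or two samples of each other; curvature
  features are more faithfully resolved at ≥60 Hz, and the generator's
  signal-path cohorts therefore default to 60 Hz.
- Blood-pressure estimation, HRV analysis, and on-device capture are out
  of scope; SBP/DBP enter only as covariates.
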