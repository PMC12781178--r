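---
title: "HRV-based deterioration risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HRV-based deterioration risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvrisk)
```

## The problem

Emergency-department patients treated for suspected infection deteriorate
unpredictably: a small fraction will need ICU admission, ventilatory support,
vasopressors, or die within the next three days, and bedside screens (SIRS,
qSOFA) discriminate poorly. Depressed heart rate variability — the loss of
beat-to-beat complexity that accompanies physiologic stress — is a usable
early signal. `hrvrisk` implements the full decision-support pipeline: from a
lead-II ECG and whatever labs were drawn, to a calibrated-looking probability
of deterioration within 72 h, or an honest refusal to produce one.

This vignette records the methods, the tunable parameters with their
defaults and units, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## From waveform to RR series

**Detector.** R peaks are found by a Pan–Tompkins-family chain: zero-phase
Butterworth band-pass (5–25 Hz, order 2), squared derivative, centred
moving-window integration (150 ms), and a segment-wise adaptive threshold
(fraction 0.25 of each 8-s segment's 99th-percentile integrated energy, with
a global floor so silent segments do not detect noise). Each fiducial is
refined to the raw-waveform maximum within ±40 ms; equal-height maxima break
to the earliest sample, for determinism. A 200 ms refractory period is
enforced, keeping the stronger of colliding candidates. The detector is
validated against planted ground truth from the template-ECG generator:
exact recovery (|Δt| ≤ 4 ms) on clean signal, precision/recall ≥ 0.99 at
20 dB SNR.

**Cleaning.** `clean_rr()` only flips validity flags — intervals are never
deleted, so downstream code can choose contiguous valid runs. Two rules:
intervals outside 300–2000 ms, and intervals deviating more than 20 % from
the median of the up-to-five preceding valid intervals. The pass is
sequential, so re-cleaning a cleaned series changes nothing (idempotence is
tested).

**Quality gates.** A predictive score requires at least 15 minutes of
*usable* recording — the sum of valid RR intervals, not wall-clock time,
because the floor exists to guarantee the HRV analysis is possible — and at
least 80 % valid intervals. The 15-min floor is a study-design constant; the
80 % noise threshold is this package's own choice (the deployment criterion
was not published) and is configurable. `TOO_SHORT` takes precedence over
`TOO_NOISY`: a verdict of "too noisy" is only issued when enough usable
signal exists but the valid fraction is poor. A rhythm screen flags
AF-like irregularity (coefficient of variation of valid RR > 0.18, or more
than 60 % of successive differences above 50 ms); it is a screen standing in
for manual rhythm exclusion, not a diagnosis.

## The metric panel

Defaults, with units, all configurable and recorded into every report:

| parameter | default | notes |
|---|---|---|
| DFA scales | 4–16 beats | the short-term α1 convention |
| entropy `m` | 2 | template length |
| entropy `r` | 0.15 | fraction of the SD of the analysed sequence |
| fuzzy power | 2 | membership exponent |
| MSE scales | 1–10 | 15–40-min recordings give ~1000–3000 beats; scale 20 would leave < 100 points |
| power-law band | 1/duration … 0.04 Hz | very-low-frequency region |

The deployment's own parameter choices are not published; these defaults
follow the HRV literature's conventions and must not be read as the
clinical system's values.

**DFA α1.** The integrated, mean-centred series is split into
non-overlapping windows of *n* beats, each linearly detrended; α1 is the
slope of log₁₀F(n) against log₁₀n. Plain linear detrending biases α1
upward at small scales (on uncorrelated noise, scales 4–16 measure ≈ 0.58
rather than 0.5), so by default each F(n) is divided by its *exact*
white-noise expectation — computable in closed form from the detrending
projection applied to the within-window covariance of a random walk — and
the √n scaling restored. This modified-DFA correction brings uncorrelated
noise to 0.50 and spectrally synthesized 1/f series to ≈ 0.94 at these
scales; it can be disabled with `correct = FALSE`.

**Sample, multiscale and fuzzy entropy.** SampEn(m, r) = −ln(A/B) with
Chebyshev distances, self-matches excluded, and the standard n − m template
convention for both lengths. MSE coarse-grains by non-overlapping means and
anchors r to the scale-1 SD (the original convention — re-estimating r per
scale answers a different question); scales with fewer than 50 coarse-grained
points are marked not-computable, and the summary is the mean of the finite
curve entries. Fuzzy entropy replaces the hard threshold with the membership
exp(−(d/r)^p) and removes each template's own mean (local detrending).
Both entropies are verified to 1e-10 against independent brute-force
double-loop oracles.

**Power-law fit.** The RR tachogram is unevenly sampled by construction, so
the spectrum is estimated with the classic Lomb–Scargle periodogram (times =
beat times of valid intervals, values = RR in ms, mean removed) on the
natural grid k/T up to 0.04 Hz. The fit of log₁₀ power on log₁₀ frequency is
performed on log-spaced frequency bins, merging adjacent bins until each
holds at least 5 ordinates: with near-equal ordinate counts the chi-squared
bias of a log bin mean is nearly constant across bins and cancels in the
slope, where unequal counts would tilt it (~+0.2 on white noise). Below 15
minutes of usable signal the band has too little low-frequency support and
the fit refuses; a band with fewer than 10 ordinates returns not-computable.

**Heart rate asymmetry.** Porta's index: the percentage of Poincaré points
below the identity line among off-identity points, using consecutive valid
pairs only; 50 is symmetric, and time reversal maps PI to 100 − PI exactly
(tested). An increasing ramp gives 0 under this below-line convention.
Guzik's (distance-weighted) index is also computed and stored, but no model
consumes it; which asymmetry variant the deployment used is unspecified, so
one had to be chosen as primary.

**Not-computable values** propagate as explicit `NA` markers with recorded
reasons — never as silent zeros — and `compute_panel()` refuses with a typed
no-score object (not an exception) when the quality verdict is not OK, so
the no-score reporting path needs no error handling.

When some intervals are flagged invalid, the block-based metrics (DFA,
entropies) run on the longest contiguous valid run rather than stitching
across gaps, which would manufacture fluctuations at exactly the scales
those metrics probe; the mean and asymmetry use all valid intervals/pairs,
and the spectral fit uses the valid intervals at their true times. All
metrics are invariant to prepending invalid-flagged intervals (tested).

## The model cascade

Five logistic models share a common structure — standardized features, a
logistic link — and differ in their feature sets:

| model | HRV features | labs | reference AUC |
|---|---|---|---|
| 1 | DFA α1, MSE | lactate, INR, creatinine | 0.84 |
| 2 | DFA α1, MSE, fuzzy entropy | lactate, creatinine | 0.83 |
| 3 | DFA α1, MSE, mean R–R | INR, creatinine | 0.81 |
| 4 | DFA α1, fuzzy entropy, power-law R², respiratory rate | lactate | 0.82 |
| 5 | DFA α1, MSE, mean R–R, power-law slope, asymmetry index | — | 0.80 |

Selection is by lab availability: the lowest-numbered model whose labs are
all present wins (more labs preferred — the reference AUCs decrease down the
table). The three availability patterns outside the table (creatinine only,
INR only, lactate + INR) resolve by the same subset rule rather than
erroring; a tool whose purpose is to use "whatever labs are available"
should not refuse on an unlisted combination. A not-computable HRV feature
drops the cascade to the next model whose features all exist; if none
qualifies, a typed no-score results. The respiratory rate consumed by model
4 is the triage vital, not an ECG-derived estimate.

The reference AUCs are display metadata from the original derivation data,
which (like the pretrained coefficients) are not public. `fit_models()`
therefore exists: five separate maximum-likelihood fits (whether the
deployment shared one coefficient set across models is unknown; separate
fits are the cleaner assumption), each on the subset of patients whose labs
admit that model, with standardization estimated on the training subset and
stored in the spec. Fitting refuses below 50 events (separation risk) and
detects (quasi-)separation, suggesting the optional ridge penalty
(`config = list(l2 = ...)`).

## Screening and outcome labelling

The SIRS count implements four criteria — temperature > 38.0 / < 36.0 °C,
heart rate > 90 bpm, respiratory rate > 20/min or PaCO₂ < 32 mmHg, and
WBC > 12,000/mm³ / < 4,000/mm³ / band forms ≥ 10 % — each contributing at
most 1 however many sub-conditions hold. Inequalities are strict as printed;
the band threshold is read inclusively ("10 % immature forms" carries no
operator) and is configurable. Missing optional labs simply cannot satisfy
their criterion. Eligibility = age ≥ 18, SIRS ≥ 2, bloodwork ordered, and no
exclusion (DNR/DNI, non-sinus/paced rhythm, outcome within 1 h of arrival);
ineligible verdicts always list every failed reason.

The 72-h outcome labeler qualifies an event when it *starts* inside the
window (the definition counts "initiation of" therapies) and meets its
kind's minimum duration — ICU ≥ 24 h, NIPPV ≥ 1 h, vasopressors/inotropes
≥ 1 h; intubation and death have none — with the duration free to extend
beyond the window. Hospital readmission is deliberately excluded from the
qualifying set (the definition does not list it) but surfaced as a separate
field, since enrolment summaries sometimes tabulate it alongside outcomes.

## Reports

Every report carries the patient summary, each lab with a value or an
explicit "not drawn" marker (absence is the common case: availability in
the enrolment setting ran 97 % creatinine, 56 % lactate, 28 % INR), the HRV
section with parameters, the quality section, and provenance (tool version,
configuration hash, seed, optional timestamp). Exactly one of a risk section
or a no-score notice is present. The definition of deterioration is embedded
verbatim from configuration in every report and cannot be disabled — early
users flagged its absence — only edited. Risk is shown both as a probability
and a one-decimal percentage; no high/medium/low banding is invented. The
JSON rendering is loss-less (`parse_report()` recovers an equal object) and
byte-deterministic given identical inputs; the timestamp is an injected
provenance field excluded from determinism comparisons. Section ordering
(risk at top) follows user feedback that the report header should carry the
important information.

## The synthetic-data generator

`gen_rr()` produces white, 1/f (fixed spectral amplitudes ∝ f^(−1/2),
random phases), AR(1), and "physiologic" series — a mean level plus
baroreflex-band (0.095 Hz) and respiratory (0.24 Hz) oscillations with
white residual — clipped to 300–2000 ms. `gen_ecg()` places a fixed P-QRS-T
Gaussian template (1 mV R wave) at the beat times and returns the planted
truth, with optional Gaussian noise at a stated SNR and sinusoidal baseline
wander. `gen_cohort()` draws, per patient: an outcome at 6 % prevalence;
HRV features and labs from class-conditional distributions shifted by
configurable standardized effect sizes (deteriorators lower in
variability/complexity metrics, higher in labs); independent per-lab
missingness at 97/56/28 % (only marginal rates are known, hence
independence); vitals guaranteeing the SIRS ≥ 2 inclusion; and a recording
duration from a truncated normal (mean 25, SD 7, bounds 15–40 min). The
default effect size (0.55 SD per feature) was chosen once to give the
lab-free model a demonstration AUC near 0.8 and is explicitly not an
estimate of any clinical effect; the true class-conditional HRV
distributions live in the unpublished derivation data, and these are
labelled synthetic stand-ins. An alternative `"logistic"` mechanism draws
the outcome from a known logistic model on the features and attaches the
ground truth, which is what the parameter-recovery checks consume.

Feature-level simulation is the default for model tests (fast,
statistically controlled); signal-level simulation (RR → ECG → detector →
panel) is reserved for end-to-end tests, because the oscillator model's
metric distributions are not calibrated to patients. What the generator does
**not** emulate: 12-lead morphology, arrhythmias beyond irregular-RR
fixtures, ectopy patterns, lab–lab correlation, drug effects, or any
realistic joint distribution of HRV metrics. Passing tests therefore
demonstrate correctness of the computations and the pipeline's contracts on
controlled signals — not clinical performance on real patients.

## Problem sizes and verification

The test suite verifies: entropy implementations against brute-force
oracles (20 series of n = 300, agreement to 1e-10); DFA α1 analytic limits
(50 seeds of n = 4096: white 0.45–0.55, 1/f 0.90–1.10); the MSE scale-1
identity (exact); Porta reversal antisymmetry (exact, 50 series);
power-law slope recovery (50 seeds: −1 synthesis within ±0.15 at mean
R² ≥ 0.9, white within ±0.15 of 0); detector planted-truth performance;
the full 8-pattern cascade truth table; no-score behaviour for every
sub-15-min input including exit-code semantics of the CLI; coefficient
recovery on n = 20,000 logistic cohorts (±10 %, held-out AUC within ±0.02
of the oracle AUC from the true probabilities, chance-level AUC on null
cohorts); generator fidelity at n = 10,000 (3 binomial SE); and
byte-identical artifacts under identical seed and configuration. These
sizes were chosen to make Monte-Carlo error comfortably smaller than each
acceptance band while keeping the suite quick to run.

## Known limitations

* The quality thresholds (80 % valid fraction) and rhythm-screen cutoffs
  stand in for unpublished deployment criteria.
* Metric parameter defaults are literature conventions, not the clinical
  system's values; results are parameter-sensitive in the usual ways
  (notably r for the entropies and the DFA fitting range).
* Shipped/demonstration model banks are synthetic fits: the probabilities
  they produce are structurally meaningful but clinically meaningless.
* WFDB support is limited to format 16, EDF to identical-rate channels;
  both are read-only by design.
* The detector targets adult sinus-rhythm lead II with a dominant R wave;
  paced rhythms and low-amplitude QRS morphologies are out of scope (the
  rhythm screen exists to catch the former).
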