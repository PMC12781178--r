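# hrvrisk

Heart rate variability (HRV) decision support for emergency-department
patients with suspected infection.

Clinicians in the ED must judge, often within hours, whether a patient
treated for infection will deteriorate — and bedside screens such as SIRS or
qSOFA have poor prognostic accuracy. Reduced beat-to-beat variability of the
heart is a physiologic marker of stress and diminished reserve, and combining
nonlinear HRV metrics with whatever laboratory markers happen to have been
drawn yields a usable short-term risk estimate. `hrvrisk` implements that
pipeline end to end:

1. **Signal I/O** — lead-II ECG from CSV, WFDB (format 16) or EDF; RR
   intervals from plain text. Canonical units: mV, seconds, milliseconds.
2. **Beat detection and gating** — a Pan–Tompkins-family R-peak detector,
   artifact flagging of the RR series, and the quality gates that decide
   whether a predictive score may be produced (≥ 15 min of usable signal,
   ≥ 80 % valid intervals, a sinus-likeness screen).
3. **HRV metric panel** — short-term detrended fluctuation analysis
   (DFA α1), multiscale entropy (MSE), fuzzy entropy, mean R–R interval,
   a Lomb–Scargle power-law fit of the RR spectrum (slope and goodness of
   fit R²), and Poincaré heart rate asymmetry (Porta's index, with Guzik's
   stored as a courtesy).
4. **Risk models** — five logistic models keyed to lab availability
   (lactate, INR, creatinine), selected by a cascade that prefers the model
   using the most labs; output is the probability of clinical deterioration
   within 72 h, `p = logistic(β₀ + Σ βᵢ zᵢ)` on standardized features.
5. **Screening and outcomes** — the SIRS count, eligibility rules, and the
   72-h deterioration labeler (ICU ≥ 24 h, NIPPV ≥ 1 h, intubation,
   vasopressors/inotropes ≥ 1 h, death).
6. **Reports** — a structured decision-support report that always carries
   the clinical sections and the definition of deterioration, with either a
   risk section or an explicit no-score notice naming the failed gate.
7. **Synthetic data** — RR series with controlled correlation structure,
   template ECG with planted ground-truth beats, and patient cohorts with
   configurable prevalence, lab missingness and effect sizes, so every stage
   is testable without patient data.

The pretrained coefficients of the original clinical deployment are not
public; any model bank this package fits is a **demonstration fit on
synthetic data and carries no clinical validity**.

## Worked example

```r
library(hrvrisk)

sim   <- gen_ecg(gen_rr("physiologic", 1900, 800, 30, seed = 42), 250,
                 snr_db = 25, seed = 42)        # ~25 min of synthetic lead II
rr    <- clean_rr(build_rr(detect_r_peaks(sim$ecg)))
quality <- assess_quality(rr)
#> <sa_quality> OK: 25.3 min usable (100% of intervals), rhythm SINUS_LIKE

panel <- compute_panel(rr, respiratory_rate_bpm = 18, quality = quality)
tidy(panel)
#> # A tibble: 10 × 2
#>   metric          value
#> 1 dfa_alpha1      0.676
#> 2 mse_summary     1.20
#> 3 fuzzy_entropy   2.24
#> 4 mean_rr_ms    800.
#> # …

bank  <- fit_models(gen_cohort(cohort_spec(
  n_patients = 6000, outcome_prevalence = 0.1,
  lab_availability = c(creatinine = 1, lactate = 1, inr = 1), seed = 7)))
labs  <- lab_panel(lactate_mmol_per_l = 2.1, creatinine_umol_per_l = 95,
                   inr = 1.2)
predict_risk(panel, labs, bank)
#> <sa_risk_score> p(deterioration within 72 h) = 0.219 (model 1)
```

All three labs are present, so the cascade selects model 1 (DFA α1 + MSE +
lactate, INR, creatinine); with only a lactate it would fall back to model 4,
and with no labs to the HRV-only model 5. A recording failing a quality gate
produces a report whose header carries the no-score notice instead of a
probability — run `generate_report()` and `render_report(x, "text")` to see
the full artifact.

A command-line wrapper around the same functions lives at
`inst/cli/hrvrisk.R` (subcommands `analyze`, `hrv`, `simulate`, `fit`,
`eval`, `screen`, `label`).

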