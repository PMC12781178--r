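# Shared fixtures built in code.

# Minimal hand-built HRV panel for model tests (bypasses signal processing).
make_panel <- function(dfa_alpha1 = 1.0, mse_summary = 1.5,
                       fuzzy_entropy = 1.1, mean_rr_ms = 800,
                       powerlaw_slope = -1.1, powerlaw_gof_r2 = 0.9,
                       asymmetry_index_pct = 52,
                       respiratory_rate_bpm = 18) {
  structure(
    list(dfa_alpha1 = dfa_alpha1, mse_summary = mse_summary,
         fuzzy_entropy = fuzzy_entropy, mean_rr_ms = mean_rr_ms,
         powerlaw_slope = powerlaw_slope, powerlaw_gof_r2 = powerlaw_gof_r2,
         asymmetry_index_pct = asymmetry_index_pct,
         guzik_index_pct = 50, respiratory_rate_bpm = respiratory_rate_bpm,
         mse_curve = tibble::tibble(scale = 1:10,
                                    sample_entropy = rep(1.5, 10)),
         n_valid_rr = 1500L, not_computable = list(),
         params = hrvrisk:::default_metric_params()),
    class = "hrv_panel")
}

full_labs <- function() {
  lab_panel(lactate_mmol_per_l = 2.1, creatinine_umol_per_l = 95, inr = 1.2)
}

# Demonstration bank fitted once per test run on a fully-observed cohort.
demo_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) {
      cohort <- gen_cohort(cohort_spec(
        n_patients = 3000, outcome_prevalence = 0.1,
        lab_availability = c(creatinine = 1, lactate = 1, inr = 1),
        seed = 77))
      bank <<- fit_models(cohort)
    }
    bank
  }
})

# A quality report with an OK verdict for hand-built panels.
ok_quality <- function() {
  assess_quality(clean_rr(gen_rr("physiologic", 1500, 800, 30, seed = 55)))
}
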