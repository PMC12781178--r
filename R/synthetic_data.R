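#' Generate synthetic RR-interval series
#'
#' Test signals with controlled correlation structure:
#' \describe{
#'   \item{`white`}{iid Gaussian intervals.}
#'   \item{`pink`}{spectral synthesis with power proportional to 1/f
#'     (random phases), the 1/f benchmark for DFA and spectral slopes.}
#'   \item{`ar1`}{first-order autoregression with coefficient `params$phi`.}
#'   \item{`physiologic`}{mean level plus a low-frequency oscillation
#'     (0.095 Hz, baroreflex band) and a high-frequency oscillation
#'     (0.24 Hz, respiratory sinus arrhythmia) with amplitudes
#'     `params$lf_amp_ms` / `params$hf_amp_ms`, plus white residual.}
#' }
#' Intervals are clipped to the physiologic range 300-2000 ms. Output is
#' deterministic for a given seed.
#'
#' @param kind One of `"white"`, `"pink"`, `"ar1"`, `"physiologic"`.
#' @param n Number of intervals (>= 2).
#' @param mean_ms,sd_ms Target mean and standard deviation in ms.
#' @param params Kind-specific parameters, see above.
#' @param seed Integer seed.
#' @return An [rr_series()] with all intervals flagged valid.
#' @examples
#' gen_rr("pink", 512, 800, 40, seed = 1)
#' @export
gen_rr <- function(kind = c("white", "pink", "ar1", "physiologic"), n,
                   mean_ms = 800, sd_ms = 40, params = list(), seed = 1) {
  kind <- match.arg(kind)
  if (n < 2 || sd_ms < 0) {
    sa_abort("Need n >= 2 and sd_ms >= 0.", "hrvrisk_bad_params")
  }
  rr <- withr::with_seed(seed, switch(
    kind,
    white = rnorm(n, 0, 1),
    pink = pink_noise(n),
    ar1 = {
      phi <- params$phi %||% 0.8
      x <- numeric(n)
      e <- rnorm(n)
      for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
      x
    },
    physiologic = {
      lf <- params$lf_amp_ms %||% 25
      hf <- params$hf_amp_ms %||% 35
      resid <- params$resid_sd_ms %||% 10
      t <- (seq_len(n) - 1) * mean_ms / 1000  # nominal beat clock
      (lf * sin(2 * pi * 0.095 * t) + hf * sin(2 * pi * 0.24 * t) +
         rnorm(n, 0, resid)) / max(sd_ms, 1e-12)
    }
  ))
  if (kind != "physiologic") {
    s <- sd(rr)
    if (s > 0) rr <- rr / s
  }
  out <- mean_ms + sd_ms * rr
  # degenerate request: sd 0 must give a constant series
  if (sd_ms == 0) out <- rep(mean_ms, n)
  rr_series(pmin(pmax(out, 300), 2000))
}

# 1/f spectral synthesis: fixed amplitudes ~ f^(-1/2) (power exactly ~ 1/f)
# with uniform random phases, hermitian spectrum, real inverse FFT.
pink_noise <- function(n) {
  nf <- n %/% 2
  f <- seq_len(nf)
  amp <- f^(-0.5)
  ph <- runif(nf, 0, 2 * pi)
  half <- complex(modulus = amp, argument = ph)
  if (n %% 2 == 0) {
    spec <- c(0, half[-nf], Re(half[nf]), Conj(rev(half[-nf])))
  } else {
    spec <- c(0, half, Conj(rev(half)))
  }
  Re(fft(spec, inverse = TRUE))
}

# P-QRS-T morphology as a sum of Gaussians, R peak exactly at t = 0, 1 mV.
ecg_template <- function(t) {
  g <- function(amp, mu, sig) amp * exp(-((t - mu)^2) / (2 * sig^2))
  g(0.12, -0.20, 0.045) +   # P
    g(-0.10, -0.035, 0.012) + # Q
    g(1.00, 0, 0.011) +       # R
    g(-0.18, 0.035, 0.014) +  # S
    g(0.30, 0.28, 0.065)      # T
}

#' Synthesize a template ECG with planted beat times
#'
#' Places a fixed P-QRS-T template (dominant 1 mV R deflection) at the
#' cumulative beat times of an RR series, optionally adding Gaussian noise
#' at a stated signal-to-noise ratio and sinusoidal baseline wander. The
#' planted ground-truth beat times are returned alongside the recording so
#' detector performance can be scored exactly.
#'
#' @param rr An [rr_series()] giving the beat schedule.
#' @param sampling_rate_hz Sampling rate (>= 100 Hz).
#' @param snr_db Optional signal-to-noise ratio in dB; `NULL` = noise-free.
#' @param baseline_wander Optional list with `amp_mv` and `freq_hz`.
#' @param seed Integer seed (noise realisation).
#' @return A list: `ecg` (an [ecg_recording()]) and `beat_times_s` (planted
#'   ground truth).
#' @examples
#' sim <- gen_ecg(gen_rr("white", 20, 800, 15, seed = 2), 250, snr_db = 20,
#'                seed = 2)
#' sim$ecg
#' @export
gen_ecg <- function(rr, sampling_rate_hz = 250, snr_db = NULL,
                    baseline_wander = NULL, seed = 1) {
  stopifnot(inherits(rr, "rr_series"))
  if (sampling_rate_hz < 100) {
    sa_abort("Sampling rate below 100 Hz.", "hrvrisk_bad_rate")
  }
  beats <- rr$beat_times_s - min(rr$beat_times_s) + 0.5
  dur <- max(beats) + 0.8
  t <- seq(0, dur, by = 1 / sampling_rate_hz)
  x <- numeric(length(t))
  for (b in beats) {
    lo <- max(1L, ceiling((b - 0.45) * sampling_rate_hz))
    hi <- min(length(t), floor((b + 0.55) * sampling_rate_hz))
    idx <- lo:hi
    x[idx] <- x[idx] + ecg_template(t[idx] - b)
  }
  if (!is.null(baseline_wander)) {
    x <- x + baseline_wander$amp_mv *
      sin(2 * pi * baseline_wander$freq_hz * t)
  }
  if (!is.null(snr_db)) {
    p_sig <- mean(x^2)
    x <- x + withr::with_seed(seed,
                              rnorm(length(x), 0,
                                    sqrt(p_sig / 10^(snr_db / 10))))
  }
  list(ecg = ecg_recording(x, sampling_rate_hz),
       beat_times_s = beats)
}

#' Specification of a synthetic patient cohort
#'
#' Defaults encode the enrolment conditions the pipeline is designed for:
#' 6% deterioration prevalence, marginal lab availability of 97%
#' (creatinine), 56% (lactate) and 28% (INR) masked independently per lab,
#' and recording durations from a truncated normal with mean 25, SD 7,
#' bounded to 15-40 minutes. Effect sizes are standardized class-conditional
#' shifts (deteriorators minus survivors, in units of the feature SD) with a
#' sign convention of reduced variability/complexity and elevated labs in
#' deteriorators; the default magnitude (0.55 SD per feature) is chosen to
#' yield a demonstration AUC around 0.8 for the lab-free model, and is a
#' synthetic stand-in, not an estimate of any clinical effect.
#'
#' @param n_patients Number of patients.
#' @param outcome_prevalence Probability of deterioration within 72 h.
#' @param lab_availability Named availability probabilities for
#'   `creatinine`, `lactate`, `inr`.
#' @param duration_mean_min,duration_sd_min,duration_range_min Recording
#'   duration distribution (truncated normal), minutes.
#' @param effect_sizes Named standardized shifts; names as in
#'   [model_feature_sets()] features.
#' @param mechanism `"effect_shift"` (class-conditional feature shifts,
#'   default) or `"logistic"` (outcome drawn from a known logistic model on
#'   the features; see `true_model`).
#' @param true_model For `mechanism = "logistic"`: a list with `features`,
#'   `intercept` and `coefficients` (raw scale).
#' @param seed Integer seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_patients = 1000,
                        outcome_prevalence = 0.06,
                        lab_availability = c(creatinine = 0.97,
                                             lactate = 0.56, inr = 0.28),
                        duration_mean_min = 25, duration_sd_min = 7,
                        duration_range_min = c(15, 40),
                        effect_sizes = NULL,
                        mechanism = c("effect_shift", "logistic"),
                        true_model = NULL,
                        seed = 1) {
  mechanism <- match.arg(mechanism)
  # prevalence 0 is allowed: it produces a zero-event cohort on which
  # downstream fitting must refuse
  if (outcome_prevalence < 0 || outcome_prevalence >= 1) {
    sa_abort("outcome_prevalence must be in [0, 1).", "hrvrisk_bad_params")
  }
  if (any(lab_availability < 0 | lab_availability > 1) ||
      !all(c("creatinine", "lactate", "inr") %in% names(lab_availability))) {
    sa_abort("lab_availability must name creatinine, lactate, inr in [0,1].",
             "hrvrisk_bad_params")
  }
  if (diff(duration_range_min) <= 0) {
    sa_abort("duration_range_min must be ordered.", "hrvrisk_bad_params")
  }
  defaults <- c(dfa_alpha1 = -0.55, mse_summary = -0.55,
                fuzzy_entropy = -0.55, mean_rr_ms = -0.55,
                powerlaw_slope = -0.55, powerlaw_gof_r2 = -0.55,
                asymmetry_index_pct = 0.55, respiratory_rate_bpm = 0.55,
                lactate_mmol_per_l = 0.8, creatinine_umol_per_l = 0.5,
                inr = 0.5)
  es <- defaults
  if (!is.null(effect_sizes)) es[names(effect_sizes)] <- effect_sizes
  structure(
    list(n_patients = n_patients, outcome_prevalence = outcome_prevalence,
         lab_availability = lab_availability,
         duration_mean_min = duration_mean_min,
         duration_sd_min = duration_sd_min,
         duration_range_min = duration_range_min,
         effect_sizes = es, mechanism = mechanism, true_model = true_model,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Control-class (survivor) feature distributions. Raw features are smooth
# monotone transforms of a standard-normal latent z; labs are log-normal so
# they stay positive.
cohort_feature_defs <- function() {
  list(
    dfa_alpha1 = function(z) 1.05 + 0.25 * z,
    mse_summary = function(z) 1.6 + 0.35 * z,
    fuzzy_entropy = function(z) 1.1 + 0.3 * z,
    mean_rr_ms = function(z) 760 + 90 * z,
    powerlaw_slope = function(z) -1.1 + 0.3 * z,
    powerlaw_gof_r2 = function(z) plogis(2.2 + 0.8 * z),
    asymmetry_index_pct = function(z) pmin(pmax(52 + 8 * z, 0), 100),
    respiratory_rate_bpm = function(z) pmax(20 + 4 * z, 8),
    lactate_mmol_per_l = function(z) exp(log(1.6) + 0.45 * z),
    creatinine_umol_per_l = function(z) exp(log(95) + 0.35 * z),
    inr = function(z) exp(log(1.15) + 0.22 * z)
  )
}

#' Generate a synthetic patient cohort
#'
#' One row per patient: demographics and vitals (drawn so that every patient
#' meets the SIRS >= 2 inclusion criterion), HRV features and labs from
#' class-conditional distributions shifted by the spec's effect sizes (or,
#' under the `"logistic"` mechanism, an outcome drawn from a known logistic
#' model - the ground truth for parameter-recovery checks, attached as the
#' `"true_model"` attribute), independent per-lab missingness at the
#' configured availability rates, and a recording duration from the
#' truncated normal. Deterministic per `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with attribute `"spec"` (and `"true_model"` under the
#'   logistic mechanism).
#' @examples
#' cohort <- gen_cohort(cohort_spec(n_patients = 200, seed = 42))
#' dplyr::count(cohort, outcome)
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  defs <- cohort_feature_defs()
  feats <- names(defs)
  withr::with_seed(spec$seed, {
    z <- matrix(rnorm(n * length(feats)), n,
                dimnames = list(NULL, feats))
    transform_all <- function(z) {
      tibble::as_tibble(purrr::map(setNames(feats, feats),
                                   function(f) defs[[f]](z[, f])))
    }
    if (spec$mechanism == "effect_shift") {
      outcome <- rbinom(n, 1, spec$outcome_prevalence) == 1
      for (f in feats) {
        z[, f] <- z[, f] + spec$effect_sizes[f] * outcome
      }
      X <- transform_all(z)
      truth <- NULL
    } else {
      X <- transform_all(z)
      tm <- spec$true_model
      if (is.null(tm)) {
        sa_abort("logistic mechanism requires `true_model`.",
                 "hrvrisk_bad_params")
      }
      eta <- tm$intercept +
        as.matrix(X[tm$features]) %*% tm$coefficients
      p_true <- plogis(drop(eta))
      outcome <- rbinom(n, 1, p_true) == 1
      truth <- list(features = tm$features, intercept = tm$intercept,
                    coefficients = tm$coefficients, p_true = p_true)
    }
    # inclusion by construction: fever plus tachycardia => SIRS >= 2
    cohort <- dplyr::bind_cols(
      tibble::tibble(
        patient_id = seq_len(n),
        age_years = rtruncnorm1(n, 61.3, 16, 18, 100),
        temperature_c = runif(n, 38.1, 39.6),
        heart_rate_bpm = runif(n, 91, 135),
        duration_min = rtruncnorm1(n, spec$duration_mean_min,
                                   spec$duration_sd_min,
                                   spec$duration_range_min[1],
                                   spec$duration_range_min[2]),
        outcome = outcome
      ),
      X
    )
    avail <- spec$lab_availability
    mask <- function(v, p) ifelse(runif(n) < p, v, NA_real_)
    cohort$creatinine_umol_per_l <- mask(cohort$creatinine_umol_per_l,
                                         avail["creatinine"])
    cohort$lactate_mmol_per_l <- mask(cohort$lactate_mmol_per_l,
                                      avail["lactate"])
    cohort$inr <- mask(cohort$inr, avail["inr"])
    attr(cohort, "spec") <- spec
    if (!is.null(truth)) attr(cohort, "true_model") <- truth
    cohort
  })
}
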