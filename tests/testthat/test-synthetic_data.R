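test_that("RR generators honour moments, determinism and clipping", {
  const <- gen_rr("white", 100, 800, 0, seed = 1)
  expect_equal(const$rr_ms, rep(800, 100))

  sds <- purrr::map_dbl(1:10, function(s) {
    sd(gen_rr("white", 4096, 800, 40, seed = s)$rr_ms)
  })
  expect_lt(abs(mean(sds) - 40) / 40, 0.05)

  a <- gen_rr("pink", 512, 800, 40, seed = 4)
  b <- gen_rr("pink", 512, 800, 40, seed = 4)
  c <- gen_rr("pink", 512, 800, 40, seed = 5)
  expect_identical(a$rr_ms, b$rr_ms)
  expect_false(identical(a$rr_ms, c$rr_ms))

  wild <- gen_rr("white", 2000, 800, 600, seed = 6)
  expect_true(all(wild$rr_ms >= 300 & wild$rr_ms <= 2000))

  expect_error(gen_rr("white", 1, 800, 10), class = "hrvrisk_bad_params")
})

test_that("pink synthesis has a 1/f spectrum by an independent estimator", {
  # oracle: ordinary periodogram of the evenly-indexed series via spec.pgram
  slopes <- purrr::map_dbl(1:10, function(s) {
    x <- gen_rr("pink", 4096, 800, 40, seed = s)$rr_ms
    sp <- stats::spec.pgram(x, plot = FALSE, taper = 0, detrend = TRUE)
    keep <- sp$freq > 0.002 & sp$freq < 0.4
    unname(coef(lm(log10(sp$spec[keep]) ~ log10(sp$freq[keep])))[2])
  })
  expect_lt(abs(mean(slopes) + 1), 0.15)
})

test_that("ar1 and physiologic kinds produce the advertised structure", {
  ar <- gen_rr("ar1", 2000, 800, 40, params = list(phi = 0.9), seed = 7)
  expect_gt(stats::acf(ar$rr_ms, plot = FALSE)$acf[2], 0.7)
  ph <- gen_rr("physiologic", 2000, 800, 30, seed = 8)
  cv <- sd(ph$rr_ms) / mean(ph$rr_ms)
  expect_lt(cv, 0.1)  # smooth, sinus-like
  expect_equal(rhythm_screen(ph), "SINUS_LIKE")
})

test_that("template ECG plants ground truth and is deterministic per seed", {
  rr <- gen_rr("white", 30, 800, 20, seed = 9)
  s1 <- gen_ecg(rr, 250, snr_db = 20, seed = 9)
  s2 <- gen_ecg(rr, 250, snr_db = 20, seed = 9)
  expect_identical(s1$ecg$samples_mv, s2$ecg$samples_mv)
  s3 <- gen_ecg(rr, 250, snr_db = 20, seed = 10)
  expect_false(identical(s1$ecg$samples_mv, s3$ecg$samples_mv))
  expect_length(s1$beat_times_s, 31)
  expect_error(gen_ecg(rr, 80), class = "hrvrisk_bad_rate")
})

test_that("detector performance degrades monotonically with heavy noise", {
  rr <- gen_rr("white", 119, 800, 20, seed = 11)
  f1 <- function(snr) {
    sim <- gen_ecg(rr, 250, snr_db = snr, seed = 11)
    sc <- tryCatch(
      match_beats(detect_r_peaks(sim$ecg), sim$beat_times_s),
      error = function(e) list(precision = 0, recall = 0))
    2 / (1 / max(sc$precision, 1e-9) + 1 / max(sc$recall, 1e-9))
  }
  hi <- f1(20); lo <- f1(-10)
  expect_gte(hi, 0.99)
  expect_lt(lo, hi)
})

test_that("cohorts reproduce availability, prevalence and duration bounds", {
  cohort <- gen_cohort(cohort_spec(n_patients = 4000, seed = 21))
  expect_equal(nrow(cohort), 4000)
  # loose 4-SE checks at this n; the calibrated check runs at n = 10,000
  p <- c(creatinine = 0.97, lactate = 0.56, inr = 0.28)
  for (lab in names(p)) {
    col <- c(creatinine = "creatinine_umol_per_l",
             lactate = "lactate_mmol_per_l", inr = "inr")[[lab]]
    se <- sqrt(p[[lab]] * (1 - p[[lab]]) / 4000)
    expect_lt(abs(mean(!is.na(cohort[[col]])) - p[[lab]]), 4 * se)
  }
  expect_lt(abs(mean(cohort$outcome) - 0.06),
            4 * sqrt(0.06 * 0.94 / 4000))
  expect_true(all(cohort$duration_min >= 15 & cohort$duration_min <= 40))
  # inclusion criterion by construction
  sirs_ok <- cohort$temperature_c > 38 & cohort$heart_rate_bpm > 90
  expect_true(all(sirs_ok))
})

test_that("cohorts are deterministic per seed and distinct across seeds", {
  a <- gen_cohort(cohort_spec(n_patients = 300, seed = 5))
  b <- gen_cohort(cohort_spec(n_patients = 300, seed = 5))
  c <- gen_cohort(cohort_spec(n_patients = 300, seed = 6))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$dfa_alpha1, c$dfa_alpha1))
})

test_that("class-conditional shifts match the configured effect sizes", {
  spec <- cohort_spec(n_patients = 30000, outcome_prevalence = 0.3, seed = 31)
  cohort <- gen_cohort(spec)
  # dfa_alpha1 is affine in its latent (sd 0.25): expected raw shift
  shift <- mean(cohort$dfa_alpha1[cohort$outcome]) -
    mean(cohort$dfa_alpha1[!cohort$outcome])
  expect_equal(shift, -0.55 * 0.25, tolerance = 0.05)
})

test_that("zero effect sizes give chance-level downstream discrimination", {
  es <- setNames(rep(0, 11), names(hrvrisk:::cohort_feature_defs()))
  spec <- cohort_spec(n_patients = 6000, outcome_prevalence = 0.1,
                      lab_availability = c(creatinine = 1, lactate = 1,
                                           inr = 1),
                      effect_sizes = es, seed = 32)
  cohort <- gen_cohort(spec)
  res <- cmd_eval(cohort, config = local({
    cfg <- default_config(); cfg$seed <- 32; cfg
  }))
  expect_true(all(res$auc > 0.4 & res$auc < 0.6))
})
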