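test_that("model selection maps every availability pattern deterministically", {
  combos <- tidyr::expand_grid(lactate = c(TRUE, FALSE),
                               creatinine = c(TRUE, FALSE),
                               inr = c(TRUE, FALSE))
  pick <- function(l, c, i) {
    select_model(lab_panel(
      lactate_mmol_per_l = if (l) 2 else NA,
      creatinine_umol_per_l = if (c) 90 else NA,
      inr = if (i) 1.2 else NA))
  }
  got <- purrr::pmap_int(combos, function(lactate, creatinine, inr) {
    pick(lactate, creatinine, inr)
  })
  # the five catalogued combinations
  expect_equal(pick(TRUE, TRUE, TRUE), 1L)
  expect_equal(pick(TRUE, TRUE, FALSE), 2L)
  expect_equal(pick(FALSE, TRUE, TRUE), 3L)
  expect_equal(pick(TRUE, FALSE, FALSE), 4L)
  expect_equal(pick(FALSE, FALSE, FALSE), 5L)
  # the three unlisted ones resolve by the subset rule
  expect_equal(pick(FALSE, TRUE, FALSE), 5L)  # creatinine only
  expect_equal(pick(FALSE, FALSE, TRUE), 5L)  # INR only
  expect_equal(pick(TRUE, FALSE, TRUE), 4L)   # lactate + INR
  expect_true(all(got %in% 1:5))
  # determinism
  expect_identical(got, purrr::pmap_int(combos, function(lactate, creatinine,
                                                         inr) {
    pick(lactate, creatinine, inr)
  }))
})

test_that("prediction equals the hand-computed logistic value", {
  bank <- demo_bank()
  panel <- make_panel()
  labs <- full_labs()
  score <- predict_risk(panel, labs, bank)
  expect_s3_class(score, "sa_risk_score")
  expect_equal(score$model_id, 1L)

  m <- bank$models[[1]]
  x <- c(panel$dfa_alpha1, panel$mse_summary, labs$lactate_mmol_per_l,
         labs$inr, labs$creatinine_umol_per_l)
  eta <- m$intercept + sum(m$coefficients * (x - m$center) / m$scale)
  expect_equal(score$probability, 1 / (1 + exp(-eta)), tolerance = 1e-12)
  expect_gte(score$probability, 0)
  expect_lte(score$probability, 1)
})

test_that("logistic link identities hold for hand-set coefficients", {
  feats <- c(hrvrisk::model_feature_sets()$hrv_features[[5]])
  zero <- hrvrisk:::new_model_spec(
    5, 0, setNames(rep(0, 5), feats), setNames(rep(0, 5), feats),
    setNames(rep(1, 5), feats))
  bank0 <- structure(list(models = list(zero), metadata = list()),
                     class = "sa_model_bank")
  s <- predict_risk(make_panel(), lab_panel(), bank0)
  expect_equal(s$probability, 0.5)

  sat <- hrvrisk:::new_model_spec(
    5, -50, setNames(rep(0, 5), feats), setNames(rep(0, 5), feats),
    setNames(rep(1, 5), feats))
  bank_sat <- structure(list(models = list(sat), metadata = list()),
                        class = "sa_model_bank")
  expect_lt(predict_risk(make_panel(), lab_panel(), bank_sat)$probability,
            1e-10)
})

test_that("prediction is monotone in a feature with positive coefficient", {
  bank <- demo_bank()
  m1 <- bank$models[[1]]
  expect_gt(m1$coefficients[["lactate_mmol_per_l"]], 0)
  probs <- purrr::map_dbl(c(1, 2, 4, 8), function(lac) {
    predict_risk(make_panel(),
                 lab_panel(lactate_mmol_per_l = lac,
                           creatinine_umol_per_l = 95, inr = 1.2),
                 bank)$probability
  })
  expect_true(all(diff(probs) > 0))
})

test_that("a not-computable HRV feature downgrades the cascade", {
  bank <- demo_bank()
  # labs admit model 2, but its fuzzy entropy is unavailable; models 1 and 3
  # need INR -> the cascade lands on model 5 (needs no labs, no fuzzy)
  labs <- lab_panel(lactate_mmol_per_l = 2, creatinine_umol_per_l = 95)
  panel <- make_panel(fuzzy_entropy = NA_real_)
  s <- predict_risk(panel, labs, bank)
  expect_equal(s$model_id, 5L)

  # nothing usable -> typed no-score, not an exception
  panel_none <- make_panel(dfa_alpha1 = NA_real_)
  s2 <- predict_risk(panel_none, labs, bank)
  expect_s3_class(s2, "sa_no_score")
  expect_equal(s2$reason, "FEATURES_UNAVAILABLE")

  # a no-score panel passes through
  expect_s3_class(predict_risk(sa_no_score("TOO_SHORT"), labs, bank),
                  "sa_no_score")
})

test_that("fit_models refuses sparse cohorts and records standardization", {
  few <- gen_cohort(cohort_spec(n_patients = 400, outcome_prevalence = 0.05,
                                seed = 3))
  expect_error(fit_models(few), class = "hrvrisk_too_few_events")

  bank <- demo_bank()
  expect_length(bank$models, 5)
  td <- tidy(bank)
  expect_true(all(c("term", "estimate", "raw_estimate") %in% names(td)))
  gl <- glance(bank)
  expect_equal(gl$model_id, 1:5)
  expect_equal(gl$reference_auc, c(0.84, 0.83, 0.81, 0.82, 0.80))
  expect_true(all(gl$n_events >= 50))
})

test_that("AUC matches the pairwise oracle and its invariances", {
  expect_equal(evaluate_auc(c(0.9, 0.1), c(TRUE, FALSE)), 1.0)
  expect_equal(evaluate_auc(rep(0.4, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  withr::with_seed(12, {
    scores <- round(runif(200), 2)  # rounding forces ties
    labels <- runif(200) < 0.3
  })
  expect_equal(evaluate_auc(scores, labels), oracle_auc(scores, labels),
               tolerance = 1e-12)
  expect_equal(evaluate_auc(qlogis(scores * 0.98 + 0.01), labels),
               evaluate_auc(scores, labels), tolerance = 1e-12)
  expect_error(evaluate_auc(scores, rep(TRUE, 200)),
               class = "hrvrisk_single_class")
})

test_that("AUC agrees with an independent ROC implementation", {
  withr::with_seed(13, {
    scores <- rnorm(300)
    labels <- runif(300) < plogis(scores)
  })
  ours <- evaluate_auc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("model bank serialization round-trips and validates feature sets", {
  bank <- demo_bank()
  f <- withr::local_tempfile(fileext = ".json")
  write_model_bank(bank, f)
  back <- read_model_bank(f)
  expect_equal(purrr::map_dbl(back$models, "intercept"),
               purrr::map_dbl(bank$models, "intercept"))
  expect_equal(back$models[[4]]$coefficients, bank$models[[4]]$coefficients)

  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  doc$models[[1]]$lab_features <- list("inr")
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_model_bank(f2), class = "hrvrisk_bad_format")
})
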