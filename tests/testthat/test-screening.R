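snap <- function(...) clinical_snapshot(...)

test_that("SIRS criteria count with grouping and strict inequalities", {
  expect_equal(sirs_count(snap(38.5, 95, 18, 60, wbc_per_mm3 = 9000)), 2)
  # two sub-conditions of the WBC criterion still count once
  expect_equal(sirs_count(snap(37, 80, 18, 60, wbc_per_mm3 = 13000,
                               band_fraction_pct = 12)), 1)
  # boundary values: strict ">" / "<"
  expect_equal(sirs_count(snap(37.0, 90, 20, 60, wbc_per_mm3 = 12000)), 0)
  expect_equal(sirs_count(snap(38.0, 90, 20, 60)), 0)
  # bands threshold is inclusive at 10%
  expect_equal(sirs_count(snap(37, 80, 18, 60, band_fraction_pct = 10)), 1)
  # RR/PaCO2 grouping
  expect_equal(sirs_count(snap(37, 80, 22, 60, paco2_mmhg = 30)), 1)
  # hypothermia arm
  expect_equal(sirs_count(snap(35.5, 95, 25, 60, wbc_per_mm3 = 3000)), 4)
})

test_that("missing optional labs cannot satisfy criteria but never error", {
  expect_equal(sirs_count(snap(37, 95, 18, 60)), 1)
  expect_silent(sirs_count(snap(37, 80, 18, 60)))
})

test_that("snapshot rejects implausible values on load", {
  expect_error(snap(60, 95, 18, 60), class = "hrvrisk_implausible")
  expect_error(snap(37, 95, 18, 60, wbc_per_mm3 = -5),
               class = "hrvrisk_implausible")
})

test_that("eligibility combines inclusion and exclusions with full reasons", {
  good <- snap(38.5, 95, 18, 61)
  v <- check_eligibility(good)
  expect_true(v$eligible)
  expect_length(v$reasons, 0)

  dnr <- snap(38.5, 95, 18, 61, dnr_or_dni = TRUE)
  v <- check_eligibility(dnr)
  expect_false(v$eligible)
  expect_true("DNR/DNI" %in% v$reasons)

  low_sirs <- snap(38.5, 80, 18, 61)
  v <- check_eligibility(low_sirs)
  expect_false(v$eligible)
  expect_equal(v$reasons, "SIRS < 2")

  # every ineligible verdict carries at least one reason
  bad <- snap(38.5, 95, 18, 17, bloodwork_ordered = FALSE,
              dnr_or_dni = TRUE, rhythm_excluded = TRUE)
  v <- check_eligibility(bad, early_outcome_within_1h = TRUE)
  expect_false(v$eligible)
  expect_length(v$reasons, 5)
})

test_that("deterioration labelling enforces window and duration minima", {
  tl <- function(kind, start, dur = NA) {
    episode_timeline(data.frame(kind = kind, start_h = start,
                                duration_h = dur))
  }
  expect_true(label_deterioration(tl("ICU_ADMIT", 50, 30))$deteriorated)
  expect_false(label_deterioration(tl("ICU_ADMIT", 50, 20))$deteriorated)
  expect_false(label_deterioration(tl("NIPPV", 10, 0.5))$deteriorated)
  expect_true(label_deterioration(tl("NIPPV", 10, 1))$deteriorated)
  expect_true(label_deterioration(tl("DEATH", 60))$deteriorated)
  expect_false(label_deterioration(tl("DEATH", 80))$deteriorated)
  expect_true(label_deterioration(tl("INTUBATION", 71.9, NA))$deteriorated)
  # readmission is tracked but never qualifies
  lab <- label_deterioration(tl("HOSPITAL_READMISSION", 48, NA))
  expect_false(lab$deteriorated)
  expect_true(lab$readmission)
  # duration extending beyond the window still qualifies
  expect_true(label_deterioration(tl("VASOPRESSOR_OR_INOTROPE", 71, 48))$deteriorated)
})

test_that("labelling is monotone in the window and empty at zero", {
  events <- data.frame(
    kind = c("NIPPV", "ICU_ADMIT", "DEATH"),
    start_h = c(5, 40, 90),
    duration_h = c(2, 30, NA))
  tl <- episode_timeline(events)
  windows <- c(0, 4, 6, 41, 72, 96)
  det <- purrr::map_lgl(windows, function(w) {
    label_deterioration(tl, w)$deteriorated
  })
  expect_false(det[1])
  expect_true(all(diff(det) >= 0))
  lab <- label_deterioration(tl, 72)
  expect_equal(lab$first_event_h, 5)
  expect_equal(nrow(lab$qualifying_events), 2)
})

test_that("timelines validate kinds, times and the death-duration rule", {
  expect_error(episode_timeline(data.frame(kind = "SNEEZE", start_h = 1,
                                           duration_h = NA)),
               class = "hrvrisk_bad_timeline")
  expect_error(episode_timeline(data.frame(kind = "NIPPV", start_h = -1,
                                           duration_h = 2)),
               class = "hrvrisk_bad_timeline")
  expect_error(episode_timeline(data.frame(kind = "DEATH", start_h = 1,
                                           duration_h = 5)),
               class = "hrvrisk_bad_timeline")
  empty <- episode_timeline(NULL)
  expect_false(label_deterioration(empty)$deteriorated)
})
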