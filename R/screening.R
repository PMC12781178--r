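#' Clinical snapshot for eligibility screening
#'
#' Triage vitals and screening context for one patient. Optional fields
#' (`paco2_mmhg`, `wbc_per_mm3`, `band_fraction_pct`) default to `NA`: a
#' missing value can never satisfy its criterion, but is never an error.
#' Loose physiologic plausibility bounds are enforced on construction to
#' catch unit mistakes.
#'
#' @param temperature_c Core temperature, Celsius.
#' @param heart_rate_bpm Heart rate, beats/min.
#' @param respiratory_rate_bpm Respiratory rate, breaths/min.
#' @param age_years Age in years.
#' @param paco2_mmhg,wbc_per_mm3,band_fraction_pct Optional labs: arterial
#'   CO2 tension (mmHg), white cell count (per mm3), immature band forms (%).
#' @param bloodwork_ordered Was bloodwork ordered? (inclusion requirement).
#' @param dnr_or_dni Do-not-resuscitate / do-not-intubate order present.
#' @param rhythm_excluded Non-sinus or paced rhythm precluding HRV analysis.
#' @return An object of class `"sa_snapshot"`.
#' @export
clinical_snapshot <- function(temperature_c, heart_rate_bpm,
                              respiratory_rate_bpm, age_years,
                              paco2_mmhg = NA_real_, wbc_per_mm3 = NA_real_,
                              band_fraction_pct = NA_real_,
                              bloodwork_ordered = TRUE, dnr_or_dni = FALSE,
                              rhythm_excluded = FALSE) {
  check_range <- function(v, lo, hi, nm) {
    if (!is.na(v) && (v < lo || v > hi)) {
      sa_abort(sprintf("%s = %g outside plausible range [%g, %g].",
                       nm, v, lo, hi), "hrvrisk_implausible")
    }
  }
  check_range(temperature_c, 25, 45, "temperature_c")
  check_range(heart_rate_bpm, 10, 300, "heart_rate_bpm")
  check_range(respiratory_rate_bpm, 2, 80, "respiratory_rate_bpm")
  check_range(age_years, 0, 120, "age_years")
  check_range(paco2_mmhg, 5, 150, "paco2_mmhg")
  check_range(wbc_per_mm3, 0, 5e5, "wbc_per_mm3")
  check_range(band_fraction_pct, 0, 100, "band_fraction_pct")
  structure(
    list(temperature_c = temperature_c, heart_rate_bpm = heart_rate_bpm,
         respiratory_rate_bpm = respiratory_rate_bpm, age_years = age_years,
         paco2_mmhg = paco2_mmhg, wbc_per_mm3 = wbc_per_mm3,
         band_fraction_pct = band_fraction_pct,
         bloodwork_ordered = isTRUE(bloodwork_ordered),
         dnr_or_dni = isTRUE(dnr_or_dni),
         rhythm_excluded = isTRUE(rhythm_excluded)),
    class = "sa_snapshot"
  )
}

#' SIRS criterion count
#'
#' Counts how many of the four systemic-inflammatory-response criteria a
#' snapshot meets: (1) temperature > 38.0 or < 36.0 C; (2) heart rate >
#' 90 bpm; (3) respiratory rate > 20/min or PaCO2 < 32 mmHg; (4) WBC >
#' 12,000/mm3, < 4,000/mm3, or >= 10% band forms. Each criterion contributes
#' at most 1 however many of its sub-conditions hold. Inequalities are
#' strict except the band threshold, which is read as "at least 10%".
#' Missing optional values simply cannot satisfy their sub-condition.
#'
#' @param snapshot An [clinical_snapshot()].
#' @return Integer in 0..4.
#' @examples
#' sirs_count(clinical_snapshot(38.5, 95, 18, 60, wbc_per_mm3 = 9000))  # 2
#' @export
sirs_count <- function(snapshot) {
  stopifnot(inherits(snapshot, "sa_snapshot"))
  met <- function(x, f) !is.na(x) && f(x)
  c1 <- met(snapshot$temperature_c, function(v) v > 38.0 || v < 36.0)
  c2 <- met(snapshot$heart_rate_bpm, function(v) v > 90)
  c3 <- met(snapshot$respiratory_rate_bpm, function(v) v > 20) ||
    met(snapshot$paco2_mmhg, function(v) v < 32)
  c4 <- met(snapshot$wbc_per_mm3, function(v) v > 12000 || v < 4000) ||
    met(snapshot$band_fraction_pct, function(v) v >= 10)
  sum(c1, c2, c3, c4)
}

#' Eligibility screen
#'
#' A patient is eligible when adult (age >= 18), systemically inflamed
#' (SIRS >= 2), with bloodwork ordered, and none of the exclusions apply:
#' DNR/DNI order, a rhythm precluding HRV analysis, or having met a study
#' outcome within 1 h of arrival. Ineligible verdicts always carry the
#' complete list of failed reasons.
#'
#' @param snapshot An [clinical_snapshot()].
#' @param sirs SIRS count (see [sirs_count()]); computed from the snapshot
#'   when omitted.
#' @param early_outcome_within_1h Did the patient meet an outcome within 1 h
#'   of ED arrival?
#' @return A list with `eligible` (logical) and `reasons` (character vector,
#'   empty when eligible).
#' @export
check_eligibility <- function(snapshot, sirs = sirs_count(snapshot),
                              early_outcome_within_1h = FALSE) {
  stopifnot(inherits(snapshot, "sa_snapshot"))
  reasons <- character()
  if (snapshot$age_years < 18) reasons <- c(reasons, "age < 18")
  if (sirs < 2) reasons <- c(reasons, "SIRS < 2")
  if (!snapshot$bloodwork_ordered) reasons <- c(reasons, "no bloodwork ordered")
  if (snapshot$dnr_or_dni) reasons <- c(reasons, "DNR/DNI")
  if (snapshot$rhythm_excluded) {
    reasons <- c(reasons, "non-sinus or paced rhythm")
  }
  if (isTRUE(early_outcome_within_1h)) {
    reasons <- c(reasons, "outcome within 1 h of arrival")
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}

timeline_kinds <- c("ICU_ADMIT", "NIPPV", "INTUBATION",
                    "VASOPRESSOR_OR_INOTROPE", "DEATH",
                    "HOSPITAL_READMISSION")

#' Episode timeline of post-presentation events
#'
#' @param events A data frame with columns `kind` (one of `ICU_ADMIT`,
#'   `NIPPV`, `INTUBATION`, `VASOPRESSOR_OR_INOTROPE`, `DEATH`,
#'   `HOSPITAL_READMISSION`), `start_h` (hours from ED arrival, >= 0) and
#'   optionally `duration_h`. `DEATH` takes no duration.
#' @return A validated tibble of class `"sa_timeline"`, ordered by time.
#' @export
episode_timeline <- function(events = NULL) {
  if (is.null(events) || nrow(as.data.frame(events)) == 0) {
    events <- tibble::tibble(kind = character(), start_h = numeric(),
                             duration_h = numeric())
  }
  events <- tibble::as_tibble(events)
  if (!"duration_h" %in% names(events)) events$duration_h <- NA_real_
  if (!all(events$kind %in% timeline_kinds)) {
    sa_abort(sprintf("Unknown event kind(s): %s.",
                     paste(setdiff(events$kind, timeline_kinds),
                           collapse = ", ")), "hrvrisk_bad_timeline")
  }
  if (any(events$start_h < 0, na.rm = TRUE) ||
      any(events$duration_h < 0, na.rm = TRUE)) {
    sa_abort("Event times and durations must be non-negative.",
             "hrvrisk_bad_timeline")
  }
  if (any(events$kind == "DEATH" & !is.na(events$duration_h))) {
    sa_abort("DEATH events take no duration.", "hrvrisk_bad_timeline")
  }
  out <- dplyr::arrange(events, .data$start_h)
  class(out) <- c("sa_timeline", class(out))
  out
}

#' Label the 72-hour deterioration outcome
#'
#' An event qualifies when it starts inside the window and meets its kind's
#' minimum duration: ICU admission >= 24 h, noninvasive ventilation >= 1 h,
#' vasopressors/inotropes >= 1 h; intubation and death have no minimum. The
#' duration may extend beyond the window - only initiation must fall inside
#' it. Hospital readmission never qualifies under this definition and is
#' tracked separately via `readmission` in the result.
#'
#' @param timeline An [episode_timeline()].
#' @param window_h Outcome window in hours (default 72).
#' @return A list with `deteriorated` (logical), `qualifying_events`
#'   (tibble), `first_event_h`, and `readmission` (logical, informational).
#' @export
label_deterioration <- function(timeline, window_h = 72) {
  if (!inherits(timeline, "sa_timeline")) timeline <- episode_timeline(timeline)
  min_dur <- c(ICU_ADMIT = 24, NIPPV = 1, VASOPRESSOR_OR_INOTROPE = 1,
               INTUBATION = 0, DEATH = 0)
  q <- dplyr::filter(
    timeline,
    .data$kind != "HOSPITAL_READMISSION",
    .data$start_h < window_h,
    dplyr::coalesce(.data$duration_h, Inf) >= min_dur[.data$kind]
  )
  list(
    deteriorated = nrow(q) > 0,
    qualifying_events = tibble::as_tibble(q),
    first_event_h = if (nrow(q) > 0) min(q$start_h) else NA_real_,
    readmission = any(timeline$kind == "HOSPITAL_READMISSION" &
                        timeline$start_h < window_h)
  )
}
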