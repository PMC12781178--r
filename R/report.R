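default_deterioration_definition <- function() {
  paste(
    "Clinical deterioration within 72 h of ED presentation is any of:",
    "ICU admission for a minimum of 24 h; initiation of noninvasive",
    "positive pressure ventilation for a minimum of 1 h; endotracheal",
    "intubation; initiation of vasopressors or inotropes for a minimum of",
    "1 h; and/or death."
  )
}

#' Generate the decision-support report
#'
#' Assembles the report from whatever the pipeline produced. Exactly one of
#' a risk section or a no-score notice is present: when the quality gate
#' failed (recording too short, too noisy) or no model's features were
#' available, the notice names the failed gate while every clinical section
#' stays intact. Each lab appears with its value or an explicit "not drawn"
#' marker - absence is the common case and is first-class. The definition of
#' deterioration is always embedded (it is configurable but cannot be
#' disabled). Missing scores never raise; contradictory inputs (a score
#' without a panel, or with a failed gate) do.
#'
#' @param snapshot An [clinical_snapshot()].
#' @param labs A [lab_panel()].
#' @param quality An `"sa_quality"` from [assess_quality()].
#' @param panel An `"hrv_panel"`, an `"sa_no_score"`, or `NULL`.
#' @param score An `"sa_risk_score"`, an `"sa_no_score"`, or `NULL`.
#' @param deterioration_definition Text block embedded verbatim in every
#'   report.
#' @param config_hash,seed,timestamp Provenance fields. `timestamp` defaults
#'   to `NULL` (excluded), keeping report generation deterministic; the CLI
#'   injects the wall-clock time.
#' @return An object of class `"sa_report"`.
#' @export
generate_report <- function(snapshot, labs, quality, panel = NULL,
                            score = NULL,
                            deterioration_definition =
                              default_deterioration_definition(),
                            config_hash = NA_character_, seed = NA_integer_,
                            timestamp = NULL) {
  stopifnot(inherits(snapshot, "sa_snapshot"), inherits(labs, "lab_panel"),
            inherits(quality, "sa_quality"))
  has_panel <- inherits(panel, "hrv_panel")
  has_score <- inherits(score, "sa_risk_score")
  if (has_score && (!has_panel || quality$verdict != "OK")) {
    sa_abort("Contradictory inputs: a risk score requires a computed panel and an OK quality verdict.",
             "hrvrisk_contradictory")
  }

  lab_entry <- function(v) {
    if (is.na(v)) list(status = "not drawn", value = NA_real_)
    else list(status = "drawn", value = v)
  }
  labs_section <- lapply(unclass(labs), lab_entry)

  hrv_section <- if (has_panel) {
    m <- tidy(panel)
    list(status = "computed",
         metrics = as.list(setNames(m$value, m$metric)),
         mse_scale = panel$mse_curve$scale,
         mse_sample_entropy = panel$mse_curve$sample_entropy,
         params = lapply(panel$params, function(p)
           if (length(p) > 1) as.numeric(p) else p),
         not_computable = panel$not_computable)
  } else {
    reason <- if (inherits(panel, "sa_no_score")) panel$detail
              else "HRV analysis not performed"
    list(status = "not computed", reason = reason)
  }

  if (has_score) {
    sets <- model_feature_sets()
    i <- score$model_id
    risk_section <- list(
      probability = score$probability,
      percent_display = sprintf("%.1f%%", 100 * score$probability),
      model_id = i,
      model_description = sprintf(
        "Model %d: HRV (%s)%s", i,
        paste(sets$hrv_features[[i]], collapse = ", "),
        if (length(sets$lab_features[[i]]))
          paste0(" + labs (", paste(sets$lab_features[[i]], collapse = ", "),
                 ")") else ", no labs"),
      feature_values = score$feature_values
    )
    no_score_notice <- NULL
  } else {
    risk_section <- NULL
    no_score_notice <- if (inherits(score, "sa_no_score")) {
      score$detail
    } else if (inherits(panel, "sa_no_score")) {
      panel$detail
    } else if (quality$verdict != "OK") {
      sprintf("no predictive score: quality gate %s", quality$verdict)
    } else {
      "no predictive score computed"
    }
  }

  structure(
    list(
      schema = "hrvrisk-report/1",
      patient_summary = list(
        age_years = snapshot$age_years,
        temperature_c = snapshot$temperature_c,
        heart_rate_bpm = snapshot$heart_rate_bpm,
        respiratory_rate_bpm = snapshot$respiratory_rate_bpm,
        sirs_count = sirs_count(snapshot)
      ),
      labs_section = labs_section,
      hrv_section = hrv_section,
      risk_section = risk_section,
      no_score_notice = no_score_notice,
      deterioration_definition = deterioration_definition,
      quality_section = list(
        usable_duration_min = quality$usable_duration_min,
        usable_fraction = quality$usable_fraction,
        verdict = quality$verdict,
        rhythm_flag = quality$rhythm_flag,
        recording_duration_min = quality$recording_duration_min
      ),
      provenance = list(
        tool_version = as.character(packageVersion("hrvrisk")),
        config_hash = config_hash,
        seed = seed,
        timestamp = timestamp
      )
    ),
    class = "sa_report"
  )
}

#' @export
print.sa_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}

#' Render a report
#'
#' `"json"` produces a loss-less structured document ([parse_report()]
#' recovers an equal object); `"text"` a terminal rendering with the risk
#' (or the no-score notice) and the deterioration definition in the header
#' block. Identical inputs render byte-identically; the timestamp is an
#' injected provenance field, `NULL` unless supplied.
#'
#' @param report An `"sa_report"`.
#' @param format `"json"` or `"text"`.
#' @return A character scalar (json) or vector of lines (text).
#' @export
render_report <- function(report, format = c("json", "text")) {
  stopifnot(inherits(report, "sa_report"))
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                         digits = NA, na = "null",
                                         null = "null", pretty = TRUE)))
  }
  p <- report$patient_summary
  q <- report$quality_section
  header <- c(
    "== DETERIORATION RISK REPORT ==",
    if (!is.null(report$risk_section)) {
      sprintf("RISK OF DETERIORATION WITHIN 72 H: %.3f (%s) [%s]",
              report$risk_section$probability,
              report$risk_section$percent_display,
              report$risk_section$model_description)
    } else {
      sprintf("NO PREDICTIVE SCORE: %s", report$no_score_notice)
    },
    strwrap(paste("Definition of deterioration:",
                  report$deterioration_definition), width = 78),
    ""
  )
  labs <- purrr::imap_chr(report$labs_section, function(e, nm) {
    if (e$status == "drawn") sprintf("  %-22s %.4g", nm, e$value)
    else sprintf("  %-22s not drawn", nm)
  })
  hrv <- if (report$hrv_section$status == "computed") {
    vals <- report$hrv_section$metrics
    c(purrr::imap_chr(vals, function(v, nm) {
      if (is.null(v) || !is.finite(v)) sprintf("  %-22s not computable", nm)
      else sprintf("  %-22s %.4g", nm, v)
    }))
  } else {
    sprintf("  not computed: %s", report$hrv_section$reason)
  }
  c(header,
    "Patient",
    sprintf("  age %g y, temp %.1f C, HR %g bpm, RR %g /min, SIRS %d/4",
            p$age_years, p$temperature_c, p$heart_rate_bpm,
            p$respiratory_rate_bpm, p$sirs_count),
    "Labs",
    labs,
    "HRV metrics",
    hrv,
    "Recording quality",
    sprintf("  verdict %s (%.1f min usable, %.0f%% intervals valid, rhythm %s)",
            q$verdict, q$usable_duration_min, 100 * q$usable_fraction,
            q$rhythm_flag),
    sprintf("Provenance: hrvrisk %s, config %s, seed %s%s",
            report$provenance$tool_version, report$provenance$config_hash,
            report$provenance$seed,
            if (is.null(report$provenance$timestamp)) ""
            else paste0(", ", report$provenance$timestamp))
  )
}

#' @rdname render_report
#' @param json JSON text (or a file path to it) produced by
#'   `render_report(..., "json")`.
#' @export
parse_report <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json), collapse = "\n")
  }
  d <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(d$schema, "hrvrisk-report/1")) {
    sa_abort("Not a report document.", "hrvrisk_bad_format")
  }
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  d$patient_summary <- lapply(d$patient_summary, num)
  d$patient_summary$sirs_count <- as.integer(d$patient_summary$sirs_count)
  d$labs_section <- lapply(d$labs_section, function(e) {
    list(status = e$status, value = num(e$value))
  })
  if (identical(d$hrv_section$status, "computed")) {
    d$hrv_section$metrics <- lapply(d$hrv_section$metrics, num)
    d$hrv_section$mse_scale <- as.integer(d$hrv_section$mse_scale)
    d$hrv_section$mse_sample_entropy <-
      num_vec(d$hrv_section$mse_sample_entropy,
              length(d$hrv_section$mse_scale))
    d$hrv_section$params <- lapply(d$hrv_section$params, function(p)
      if (length(p) > 1) as.numeric(p) else p)
    d$hrv_section$not_computable <-
      lapply(d$hrv_section$not_computable, as.character)
  }
  if (!is.null(d$risk_section)) {
    d$risk_section$probability <- num(d$risk_section$probability)
    d$risk_section$model_id <- as.integer(d$risk_section$model_id)
    d$risk_section$feature_values <- lapply(d$risk_section$feature_values, num)
  }
  d$quality_section <- utils::modifyList(
    d$quality_section,
    lapply(d$quality_section[c("usable_duration_min", "usable_fraction",
                               "recording_duration_min")], num))
  d$provenance$seed <- if (is.null(d$provenance$seed)) NA_integer_
                       else as.integer(d$provenance$seed)
  d$provenance$config_hash <- if (is.null(d$provenance$config_hash))
    NA_character_ else as.character(d$provenance$config_hash)
  keep <- c("schema", "patient_summary", "labs_section", "hrv_section",
            "risk_section", "no_score_notice", "deterioration_definition",
            "quality_section", "provenance")
  structure(d[keep], class = "sa_report")
}

num_vec <- function(x, n) {
  v <- vapply(seq_len(n), function(i) {
    e <- x[[i]]
    if (is.null(e)) NA_real_ else as.numeric(e)
  }, numeric(1))
  v
}
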