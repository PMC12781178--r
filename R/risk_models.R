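#' The five-model feature catalogue
#'
#' Each model pairs a fixed HRV feature set with a lab requirement; which
#' model scores a given patient is decided solely by which labs were drawn
#' (see [select_model()]). Reference AUCs are carried as display metadata
#' from the original derivation cohort; they are never properties of models
#' refit on other data.
#'
#' @return A tibble with one row per model: `model_id`, `hrv_features`,
#'   `lab_features` (list-columns) and `reference_auc`.
#' @export
model_feature_sets <- function() {
  tibble::tibble(
    model_id = 1:5,
    hrv_features = list(
      c("dfa_alpha1", "mse_summary"),
      c("dfa_alpha1", "mse_summary", "fuzzy_entropy"),
      c("dfa_alpha1", "mse_summary", "mean_rr_ms"),
      c("dfa_alpha1", "fuzzy_entropy", "powerlaw_gof_r2",
        "respiratory_rate_bpm"),
      c("dfa_alpha1", "mse_summary", "mean_rr_ms", "powerlaw_slope",
        "asymmetry_index_pct")
    ),
    lab_features = list(
      c("lactate_mmol_per_l", "inr", "creatinine_umol_per_l"),
      c("lactate_mmol_per_l", "creatinine_umol_per_l"),
      c("inr", "creatinine_umol_per_l"),
      "lactate_mmol_per_l",
      character(0)
    ),
    reference_auc = c(0.84, 0.83, 0.81, 0.82, 0.80)
  )
}

#' Lab panel with explicit availability
#'
#' Field names carry the expected units (lactate mmol/L, creatinine umol/L,
#' INR dimensionless); unit conversion is the caller's responsibility. `NA`
#' or `NULL` marks a lab as not drawn - the common case, which the cascade
#' is designed around.
#'
#' @param lactate_mmol_per_l,creatinine_umol_per_l,inr Positive values or
#'   `NA`/`NULL` when not drawn.
#' @return An object of class `"lab_panel"`.
#' @export
lab_panel <- function(lactate_mmol_per_l = NA_real_,
                      creatinine_umol_per_l = NA_real_,
                      inr = NA_real_) {
  vals <- list(lactate_mmol_per_l = lactate_mmol_per_l %||% NA_real_,
               creatinine_umol_per_l = creatinine_umol_per_l %||% NA_real_,
               inr = inr %||% NA_real_)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.na(v) && (!is.finite(v) || v <= 0)) {
      sa_abort(sprintf("Lab '%s' must be positive and finite when present.",
                       nm), "hrvrisk_bad_lab")
    }
  }
  structure(lapply(vals, as.numeric), class = "lab_panel")
}

lab_availability <- function(labs) {
  stopifnot(inherits(labs, "lab_panel"))
  vapply(labs, function(v) !is.na(v), logical(1))
}

#' Select the predictive model for an availability pattern
#'
#' Models are ordered by preference (most labs first); the lowest-numbered
#' model whose lab requirement is fully met is chosen. Model 5 needs no labs
#' and is always eligible, so selection is total: unlisted combinations
#' (e.g. creatinine only, or lactate + INR) resolve by the same subset rule
#' rather than erroring.
#'
#' @param labs A [lab_panel()].
#' @return The selected `model_id` (integer 1-5).
#' @examples
#' select_model(lab_panel(lactate_mmol_per_l = 2.1, inr = 1.2,
#'                        creatinine_umol_per_l = 90))  # 1
#' select_model(lab_panel())                            # 5
#' @export
select_model <- function(labs) {
  avail <- lab_availability(labs)
  sets <- model_feature_sets()
  for (i in sets$model_id) {
    if (all(avail[sets$lab_features[[i]]])) return(i)
  }
  5L  # unreachable: model 5 requires nothing
}

new_model_spec <- function(model_id, intercept, coefficients, center, scale,
                           reference_auc = NA_real_, n_train = NA_integer_,
                           n_events = NA_integer_) {
  sets <- model_feature_sets()
  feats <- c(sets$hrv_features[[model_id]], sets$lab_features[[model_id]])
  stopifnot(identical(names(coefficients), feats),
            identical(names(center), feats),
            identical(names(scale), feats))
  structure(
    list(model_id = as.integer(model_id),
         hrv_features = sets$hrv_features[[model_id]],
         lab_features = sets$lab_features[[model_id]],
         intercept = as.numeric(intercept),
         coefficients = coefficients,
         center = center, scale = scale,
         reference_auc = reference_auc,
         n_train = n_train, n_events = n_events),
    class = "sa_model_spec"
  )
}

spec_features <- function(spec) c(spec$hrv_features, spec$lab_features)

# Raw-scale coefficients implied by the standardized fit.
raw_coefficients <- function(spec) {
  b <- spec$coefficients / spec$scale
  a <- spec$intercept - sum(spec$coefficients * spec$center / spec$scale)
  list(intercept = a, coefficients = b)
}

#' Predict the probability of deterioration within 72 hours
#'
#' Applies the logistic model selected by lab availability to the HRV panel
#' and labs: `p = plogis(intercept + sum(coef * z))` on standardized
#' features. If a required HRV feature could not be computed, the cascade
#' falls through to the highest-priority model whose features are all
#' available; if none is usable (or the panel itself is a no-score
#' refusal), a typed [sa_no_score()] is returned instead of an error.
#'
#' @param panel An `"hrv_panel"` from [compute_panel()] (or an
#'   `"sa_no_score"`, which is passed through).
#' @param labs A [lab_panel()].
#' @param bank An `"sa_model_bank"` from [fit_models()] or
#'   [read_model_bank()].
#' @return An object of class `"sa_risk_score"` with `probability`,
#'   `model_id` and the `feature_values` consumed, or an `"sa_no_score"`.
#' @export
predict_risk <- function(panel, labs, bank) {
  if (inherits(panel, "sa_no_score")) return(panel)
  stopifnot(inherits(panel, "hrv_panel"), inherits(bank, "sa_model_bank"))
  avail <- lab_availability(labs)
  for (spec in bank$models) {
    if (!all(avail[spec$lab_features])) next
    hrv_vals <- vapply(spec$hrv_features, function(f) panel[[f]], numeric(1))
    if (any(!is.finite(hrv_vals))) next
    lab_vals <- vapply(spec$lab_features, function(f) labs[[f]], numeric(1))
    x <- c(hrv_vals, lab_vals)
    z <- (x - spec$center) / spec$scale
    eta <- spec$intercept + sum(spec$coefficients * z)
    return(structure(
      list(probability = plogis(eta),
           model_id = spec$model_id,
           feature_values = as.list(x)),
      class = "sa_risk_score"
    ))
  }
  sa_no_score("FEATURES_UNAVAILABLE",
              "no model's required HRV features and labs were all available")
}

#' @export
print.sa_risk_score <- function(x, ...) {
  cat(sprintf("<sa_risk_score> p(deterioration within 72 h) = %.3f (model %d)\n",
              x$probability, x$model_id))
  invisible(x)
}

#' Fit the five-model bank on a labelled cohort
#'
#' For each model, a logistic regression is fit by maximum likelihood on the
#' subset of patients whose required labs (and HRV features) are present,
#' using the exact feature set of that model. Features are standardized on
#' the training subset and the (center, scale) pairs stored in the model
#' spec. The original derivation cohort and its pretrained coefficients are
#' not public, so any bank produced here is a demonstration fit on the data
#' you give it - typically a synthetic cohort - and carries no clinical
#' validity.
#'
#' @param cohort A data frame with a logical/0-1 `outcome` column plus the
#'   HRV feature and lab columns named in [model_feature_sets()] (`NA` =
#'   lab not drawn).
#' @param config Optional list: `l2` (ridge penalty; 0 = plain maximum
#'   likelihood, positive values use glmnet), `min_events` (refusal floor,
#'   default 50).
#' @return An object of class `"sa_model_bank"`.
#' @export
fit_models <- function(cohort, config = list()) {
  cohort <- tibble::as_tibble(cohort)
  cfg <- utils::modifyList(list(l2 = 0, min_events = 50), config)
  if (!"outcome" %in% names(cohort)) {
    sa_abort("Cohort must have an `outcome` column.", "hrvrisk_bad_cohort")
  }
  y_all <- as.integer(cohort$outcome)
  if (sum(y_all) < cfg$min_events) {
    sa_abort(sprintf(
      "Refusing to fit: %d events < %d minimum (complete-separation risk).",
      sum(y_all), cfg$min_events), "hrvrisk_too_few_events")
  }
  sets <- model_feature_sets()
  models <- purrr::map(sets$model_id, function(i) {
    feats <- c(sets$hrv_features[[i]], sets$lab_features[[i]])
    missing_cols <- setdiff(feats, names(cohort))
    if (length(missing_cols) > 0) {
      sa_abort(sprintf("Cohort lacks feature column(s): %s.",
                       paste(missing_cols, collapse = ", ")),
               "hrvrisk_bad_cohort")
    }
    sub <- cohort[stats::complete.cases(cohort[feats]), c("outcome", feats)]
    y <- as.integer(sub$outcome)
    if (sum(y) < cfg$min_events) {
      sa_abort(sprintf(
        "Model %d: %d events in its lab-complete subset < %d minimum.",
        i, sum(y), cfg$min_events), "hrvrisk_too_few_events")
    }
    X <- as.matrix(sub[feats])
    center <- colMeans(X)
    scale <- apply(X, 2, sd)
    if (any(scale == 0)) {
      sa_abort(sprintf("Model %d: constant feature in training data.", i),
               "hrvrisk_bad_cohort")
    }
    Z <- sweep(sweep(X, 2, center), 2, scale, "/")
    if (cfg$l2 > 0) {
      if (!requireNamespace("glmnet", quietly = TRUE)) {
        sa_abort("Ridge fitting requires the glmnet package.",
                 "hrvrisk_missing_dep")
      }
      fit <- glmnet::glmnet(Z, y, family = "binomial", alpha = 0,
                            lambda = cfg$l2, standardize = FALSE)
      beta <- as.numeric(fit$beta)
      a <- as.numeric(fit$a0)
    } else {
      fit <- suppressWarnings(stats::glm.fit(cbind(1, Z), y,
                                             family = binomial()))
      if (!fit$converged) {
        sa_abort(sprintf("Model %d logistic fit did not converge; consider config = list(l2 = ...).",
                         i), "hrvrisk_nonconvergence")
      }
      if (any(abs(fit$coefficients[-1]) > 15) ||
          any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)) {
        sa_abort(sprintf("Model %d: (quasi-)complete separation detected; refit with config = list(l2 = ...).",
                         i), "hrvrisk_separation")
      }
      beta <- fit$coefficients[-1]
      a <- fit$coefficients[1]
    }
    new_model_spec(i, a, setNames(as.numeric(beta), feats),
                   setNames(center, feats), setNames(scale, feats),
                   reference_auc = sets$reference_auc[i],
                   n_train = nrow(sub), n_events = sum(y))
  })
  structure(
    list(models = models,
         metadata = list(
           schema_version = "1",
           package_version = as.character(packageVersion("hrvrisk")),
           provenance = "demonstration fit on a synthetic cohort; not clinically validated",
           l2 = cfg$l2)),
    class = "sa_model_bank"
  )
}

#' @export
print.sa_model_bank <- function(x, ...) {
  cat("<sa_model_bank>", length(x$models), "models |",
      x$metadata$provenance, "\n")
  print(glance(x))
  invisible(x)
}

#' Tidy and summarize a model bank
#'
#' `tidy()` returns one row per coefficient with both the standardized
#' estimate and the implied raw-scale estimate; `glance()` one row per model
#' with its feature sets, training size and reference AUC metadata.
#'
#' @param x An `"sa_model_bank"`.
#' @param ... Unused.
#' @export
#' @method tidy sa_model_bank
tidy.sa_model_bank <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    raw <- raw_coefficients(m)
    tibble::tibble(
      model_id = m$model_id,
      term = c("(Intercept)", names(m$coefficients)),
      estimate = c(m$intercept, unname(m$coefficients)),
      center = c(NA, unname(m$center)),
      scale = c(NA, unname(m$scale)),
      raw_estimate = c(raw$intercept, unname(raw$coefficients))
    )
  })
}

#' @rdname tidy.sa_model_bank
#' @export
#' @method glance sa_model_bank
glance.sa_model_bank <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble::tibble(
      model_id = m$model_id,
      hrv_features = paste(m$hrv_features, collapse = ", "),
      lab_features = if (length(m$lab_features))
        paste(m$lab_features, collapse = ", ") else "none",
      n_train = m$n_train,
      n_events = m$n_events,
      reference_auc = m$reference_auc
    )
  })
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic divided by `n1 * n0`, with ties
#' counted one half: the probability that a random positive outranks a
#' random negative. Invariant under strictly increasing transforms of the
#' scores.
#'
#' @param scores Numeric risk scores.
#' @param labels Logical (or 0/1) outcome labels.
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    sa_abort("AUC needs both outcome classes present.",
             "hrvrisk_single_class")
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Serialize and load a model bank
#'
#' The bank is written as a versioned JSON document (model id, features,
#' standardization, coefficients, provenance). Loading re-validates the
#' lab/HRV feature-set invariants of the five-model catalogue.
#'
#' @param bank An `"sa_model_bank"`.
#' @param path File path.
#' @return `write_model_bank()` returns `path` invisibly;
#'   `read_model_bank()` the bank.
#' @export
write_model_bank <- function(bank, path) {
  stopifnot(inherits(bank, "sa_model_bank"))
  doc <- list(
    schema = "hrvrisk-model-bank",
    metadata = bank$metadata,
    models = purrr::map(bank$models, function(m) {
      list(model_id = m$model_id,
           hrv_features = as.list(m$hrv_features),
           lab_features = as.list(m$lab_features),
           intercept = m$intercept,
           coefficients = as.list(m$coefficients),
           center = as.list(m$center),
           scale = as.list(m$scale),
           reference_auc = m$reference_auc,
           n_train = m$n_train, n_events = m$n_events)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_bank
#' @export
read_model_bank <- function(path) {
  if (!file.exists(path)) {
    sa_abort(sprintf("Model bank not found: %s", path),
             "hrvrisk_missing_file")
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "hrvrisk-model-bank")) {
    sa_abort("Not a model bank document.", "hrvrisk_bad_format")
  }
  sets <- model_feature_sets()
  models <- purrr::map(doc$models, function(m) {
    id <- m$model_id
    if (!identical(unlist(m$lab_features) %||% character(0),
                   sets$lab_features[[id]]) ||
        !identical(unlist(m$hrv_features), sets$hrv_features[[id]])) {
      sa_abort(sprintf("Model %d feature sets do not match the catalogue.",
                       id), "hrvrisk_bad_format")
    }
    feats <- c(sets$hrv_features[[id]], sets$lab_features[[id]])
    grabv <- function(v) setNames(as.numeric(unlist(v)[feats]), feats)
    new_model_spec(id, m$intercept, grabv(m$coefficients), grabv(m$center),
                   grabv(m$scale), reference_auc = m$reference_auc,
                   n_train = m$n_train %||% NA_integer_,
                   n_events = m$n_events %||% NA_integer_)
  })
  structure(list(models = models, metadata = doc$metadata),
            class = "sa_model_bank")
}
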