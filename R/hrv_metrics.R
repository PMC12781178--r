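#' @title HRV metric panel
#' @description Nonlinear heart rate variability metrics computed over a
#'   cleaned RR series: short-term detrended fluctuation analysis (DFA
#'   alpha1), sample / multiscale / fuzzy entropy, mean RR, a Lomb-Scargle
#'   power-law fit of the RR spectrum, and Poincare-plot heart rate asymmetry.
#'   Values that cannot be computed on a given series are reported as `NA`
#'   with an explicit reason - never as silent zeros.
#' @name hrv_metrics
NULL

# Series actually analysed by the block-based metrics (DFA, entropies):
# the full interval vector when every flag is valid, otherwise the longest
# contiguous run of valid intervals. Stitching across flagged gaps would
# manufacture spurious fluctuations at exactly the scales DFA and entropy
# probe, so gaps are avoided rather than bridged.
analysis_values <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  if (all(series$valid)) return(series$rr_ms)
  r <- rle(series$valid)
  if (!any(r$values)) return(numeric(0))
  ends <- cumsum(r$lengths)
  k <- which(r$values)
  best <- k[which.max(r$lengths[k])]
  series$rr_ms[(ends[best] - r$lengths[best] + 1):ends[best]]
}

as_metric_input <- function(x) {
  if (inherits(x, "rr_series")) analysis_values(x) else as.numeric(x)
}

#' Mean RR interval
#'
#' Arithmetic mean over valid intervals only.
#'
#' @param series An [rr_series()].
#' @return Mean RR in milliseconds.
#' @export
mean_rr <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  rr <- series$rr_ms[series$valid]
  if (length(rr) == 0) {
    sa_abort("No valid RR intervals.", "hrvrisk_no_valid_rr")
  }
  mean(rr)
}

# Exact E[F^2(n)] of DFA-1 on unit-variance white noise, from the linear
# detrending projection applied to the within-window covariance of the
# integrated series. Used to remove the well-known small-scale bias
# (modified DFA): dividing F(n) by this shape and restoring n^(1/2) makes
# uncorrelated noise scale at exactly alpha = 0.5 in expectation.
dfa_white_expectation <- function(n) {
  key <- as.character(n)
  if (is.null(the$dfa_k)) the$dfa_k <- list()
  if (!is.null(the$dfa_k[[key]])) return(the$dfa_k[[key]])
  t <- seq_len(n)
  X <- cbind(1, t)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  M <- diag(n) - H
  C <- outer(t, t, pmin)
  val <- sqrt(sum(diag(M %*% C %*% M)) / n)
  the$dfa_k[[key]] <- val
  val
}

#' Short-term detrended fluctuation analysis exponent (alpha1)
#'
#' The integrated, mean-centred series is divided into non-overlapping
#' windows of `n` beats, each window linearly detrended, and the root mean
#' square residual `F(n)` computed; `alpha1` is the least-squares slope of
#' `log10 F(n)` versus `log10 n` over the short-term scales (default 4-16
#' beats). Uncorrelated noise gives 0.5, 1/f dynamics about 1. With
#' `correct = TRUE` (default) each `F(n)` is divided by its exact
#' white-noise expectation shape, removing the small-scale bias of linear
#' detrending (modified DFA).
#'
#' @param x An [rr_series()] (valid intervals are used; see Details in
#'   [hrv_metrics]) or a numeric vector, length >= 200.
#' @param scales Integer window sizes in beats.
#' @param correct Apply the finite-size white-noise correction.
#' @return The scaling exponent, or `NA` when the series has zero
#'   fluctuation at some scale (e.g. a constant series).
#' @export
dfa_alpha1 <- function(x, scales = 4:16, correct = TRUE) {
  x <- as_metric_input(x)
  if (length(x) < 200) {
    sa_abort("DFA alpha1 requires at least 200 valid intervals.",
             "hrvrisk_too_few_points")
  }
  y <- cumsum(x - mean(x))
  Fn <- vapply(scales, function(n) {
    k <- length(y) %/% n
    w <- matrix(y[seq_len(k * n)], nrow = n)
    t <- seq_len(n)
    X <- cbind(1, t)
    # residuals of per-window linear fits, all windows at once
    beta <- solve(crossprod(X), crossprod(X, w))
    res <- w - X %*% beta
    sqrt(sum(res^2) / (k * n))
  }, numeric(1))
  if (any(Fn == 0)) return(NA_real_)
  if (correct) {
    K <- vapply(scales, dfa_white_expectation, numeric(1))
    Fn <- Fn * sqrt(scales) / K
  }
  unname(coef(lm(log10(Fn) ~ log10(scales)))[2])
}

# Chebyshev-distance template match counts shared by SampEn. Counts ordered
# pairs i < j of m-length templates within r_abs, using the standard
# convention of n - m template start points for both m and m + 1.
sampen_counts <- function(x, m, r_abs) {
  n <- length(x)
  N <- n - m
  D <- matrix(0, N, N)
  for (k in 0:(m - 1)) {
    v <- x[(1:N) + k]
    D <- pmax(D, abs(outer(v, v, "-")))
  }
  B <- (sum(D <= r_abs) - N) / 2
  v <- x[(1:N) + m]
  D <- pmax(D, abs(outer(v, v, "-")))
  A <- (sum(D <= r_abs) - N) / 2
  c(A = A, B = B)
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A/B)` where `B` counts pairs of `m`-length templates
#' within Chebyshev distance `r` and `A` the pairs still matching at length
#' `m + 1`; self-matches are excluded. Lower values mean a more regular
#' series. Returns `NA` when either count is zero.
#'
#' @param x An [rr_series()] or numeric vector, >= 100 points.
#' @param m Template length (default 2).
#' @param r Match tolerance as a fraction of the standard deviation of the
#'   analysed sequence (default 0.15).
#' @return Sample entropy (nats), or `NA` when undefined.
#' @export
sample_entropy <- function(x, m = 2, r = 0.15) {
  x <- as_metric_input(x)
  if (length(x) < 100) {
    sa_abort("Sample entropy requires at least 100 points.",
             "hrvrisk_too_few_points")
  }
  if (m < 1 || r <= 0) {
    sa_abort("Need m >= 1 and r > 0.", "hrvrisk_bad_params")
  }
  sampen_abs(x, m, r * sd(x))
}

sampen_abs <- function(x, m, r_abs) {
  if (length(x) < m + 2) return(NA_real_)
  ab <- sampen_counts(x, m, r_abs)
  if (ab["A"] == 0 || ab["B"] == 0) return(NA_real_)
  unname(-log(ab["A"] / ab["B"]))
}

#' Multiscale entropy
#'
#' Sample entropy of coarse-grained versions of the series: at scale `tau`
#' the series of non-overlapping means of `tau` consecutive intervals. The
#' tolerance is anchored to `r` times the standard deviation of the scale-1
#' series and held fixed across scales (the original multiscale-entropy
#' convention; re-estimating `r` per scale answers a different question).
#' Scales whose coarse-grained series has fewer than 50 points are marked
#' `NA`. The summary is the mean of the finite curve entries.
#'
#' @inheritParams sample_entropy
#' @param max_scale Largest coarse-graining factor (default 10; a 15-40 min
#'   recording yields roughly 1000-3000 beats, so scale 10 retains >= 100
#'   points while scale 20 would not).
#' @return A list with `curve` (a tibble of `scale`, `sample_entropy`) and
#'   `summary` (mean of finite entries).
#' @export
multiscale_entropy <- function(x, max_scale = 10, m = 2, r = 0.15) {
  x <- as_metric_input(x)
  if (length(x) < 100) {
    sa_abort("Multiscale entropy requires at least 100 points at scale 1.",
             "hrvrisk_too_few_points")
  }
  r_abs <- r * sd(x)
  ent <- vapply(seq_len(max_scale), function(tau) {
    k <- length(x) %/% tau
    if (k < 50) return(NA_real_)
    cg <- colMeans(matrix(x[seq_len(k * tau)], nrow = tau))
    sampen_abs(cg, m, r_abs)
  }, numeric(1))
  curve <- tibble::tibble(scale = seq_len(max_scale), sample_entropy = ent)
  fin <- ent[is.finite(ent)]
  list(curve = curve,
       summary = if (length(fin)) mean(fin) else NA_real_)
}

#' Fuzzy entropy
#'
#' A sample-entropy variant in which each template pair contributes a smooth
#' membership `exp(-(d/r)^p)` instead of a hard threshold, and each template
#' has its own mean removed before distances are taken (local detrending),
#' making the measure robust to baseline drift. Defined as
#' `-ln(Phi_{m+1} / Phi_m)` with `Phi` the mean pairwise membership.
#'
#' @inheritParams sample_entropy
#' @param fuzzy_power Exponent `p` of the membership function (default 2).
#' @return Fuzzy entropy (nats); 0 for a constant series.
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.15, fuzzy_power = 2) {
  x <- as_metric_input(x)
  if (length(x) < 100) {
    sa_abort("Fuzzy entropy requires at least 100 points.",
             "hrvrisk_too_few_points")
  }
  s <- sd(x)
  r_abs <- if (s > 0) r * s else r  # constant series: any r gives 0
  n <- length(x)
  N <- n - m
  phi <- function(len) {
    tpl <- vapply(0:(len - 1), function(k) x[(1:N) + k], numeric(N))
    tpl <- tpl - rowMeans(tpl)
    D <- matrix(0, N, N)
    for (k in seq_len(len)) {
      D <- pmax(D, abs(outer(tpl[, k], tpl[, k], "-")))
    }
    mu <- exp(-(D / r_abs)^fuzzy_power)
    (sum(mu) - N) / (N * (N - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}

# Classic Lomb-Scargle periodogram for unevenly sampled data.
lomb_scargle <- function(t, y, freqs) {
  y <- y - mean(y)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
}

#' Power-law fit of the RR spectrum
#'
#' Lomb-Scargle periodogram of the unevenly sampled RR tachogram (times =
#' beat times of valid intervals, values = RR in ms, mean removed), followed
#' by a least-squares line in log10 power versus log10 frequency over the
#' band from `1/duration` to `f_max`. Periodogram ordinates are averaged in
#' log-spaced frequency bins before fitting; adjacent bins are merged until
#' each holds at least `min_per_bin` ordinates, which keeps the chi-squared
#' log-bias of the bin means nearly constant across bins so it cancels in
#' the slope. Returns the slope and the R-squared of the line.
#'
#' @param series An [rr_series()] with at least `min_duration_min` minutes of
#'   usable (valid-interval) duration.
#' @param f_max Upper band edge in Hz (default 0.04, the
#'   very-low-frequency ceiling).
#' @param n_bins Number of logarithmic frequency bins (before merging).
#' @param min_per_bin Minimum ordinates per merged bin.
#' @param min_points Minimum number of periodogram ordinates in the band.
#' @param min_duration_min Usable-duration precondition, minutes.
#' @return A list with `slope`, `r2`, `n_freqs`. Both values are `NA` when
#'   the band holds fewer than `min_points` ordinates.
#' @export
powerlaw_fit <- function(series, f_max = 0.04, n_bins = 20, min_per_bin = 5,
                         min_points = 10, min_duration_min = 15) {
  stopifnot(inherits(series, "rr_series"))
  usable_min <- sum(series$rr_ms[series$valid]) / 60000
  if (usable_min < min_duration_min) {
    sa_abort(sprintf(
      "Power-law fit requires >= %g min usable duration (got %.1f): insufficient low-frequency support.",
      min_duration_min, usable_min), "hrvrisk_too_short")
  }
  t <- series$beat_times_s[-1][series$valid]
  y <- series$rr_ms[series$valid]
  T_span <- max(t) - min(t)
  freqs <- seq_len(floor(T_span * f_max)) / T_span
  if (length(freqs) < min_points) {
    return(list(slope = NA_real_, r2 = NA_real_, n_freqs = length(freqs)))
  }
  p <- lomb_scargle(t, y, freqs)
  ok <- p > 0
  freqs <- freqs[ok]; p <- p[ok]
  edges <- exp(seq(log(min(freqs) * 0.999), log(max(freqs) * 1.001),
                   length.out = n_bins + 1))
  bin <- cut(freqs, edges, labels = FALSE)
  # merge sparse adjacent bins (low frequencies) up to min_per_bin ordinates
  counts <- table(factor(bin, levels = seq_len(n_bins)))
  merged <- integer(n_bins)
  grp <- 1L
  acc <- 0L
  for (b in seq_len(n_bins)) {
    merged[b] <- grp
    acc <- acc + counts[b]
    if (acc >= min_per_bin) {
      grp <- grp + 1L
      acc <- 0L
    }
  }
  if (acc > 0 && grp > 1) merged[merged == grp] <- grp - 1L
  df <- tibble::tibble(f = freqs, p = p, bin = merged[bin]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      lf = mean(log10(.data$f)),
      lp = log10(mean(.data$p)),
      .groups = "drop"
    )
  if (nrow(df) < 3) {
    return(list(slope = NA_real_, r2 = NA_real_, n_freqs = length(freqs)))
  }
  fit <- lm(lp ~ lf, data = df)
  list(slope = unname(coef(fit)[2]),
       r2 = summary(fit)$r.squared,
       n_freqs = length(freqs))
}

#' Heart rate asymmetry indices (Porta, Guzik)
#'
#' From consecutive valid RR pairs `(RR_i, RR_{i+1})` in the Poincare plot:
#' Porta's index is the percentage of points below the line of identity
#' (decelerations shorter than the preceding interval) among points off the
#' identity line; Guzik's index is the percentage of the total off-identity
#' distance contributed by points above the line. 50 indicates symmetry.
#'
#' @param series An [rr_series()] with at least `min_pairs` consecutive valid
#'   pairs.
#' @param type `"porta"` (default) or `"guzik"`.
#' @param min_pairs Minimum number of consecutive valid pairs.
#' @return Index in percent, or `NA` when every point lies on the identity
#'   line.
#' @export
asymmetry_index <- function(series, type = c("porta", "guzik"),
                            min_pairs = 100) {
  type <- match.arg(type)
  stopifnot(inherits(series, "rr_series"))
  nrr <- length(series$rr_ms)
  ok <- series$valid[-nrr] & series$valid[-1]
  a <- series$rr_ms[-nrr][ok]   # x: RR_i
  b <- series$rr_ms[-1][ok]     # y: RR_{i+1}
  if (length(a) < min_pairs) {
    sa_abort(sprintf("Asymmetry index requires >= %d consecutive valid pairs.",
                     min_pairs), "hrvrisk_too_few_points")
  }
  off <- b != a
  if (!any(off)) return(NA_real_)
  if (type == "porta") {
    100 * sum(b < a) / sum(off)
  } else {
    d <- (b - a) / sqrt(2)      # signed distance to identity line
    100 * sum(d[d > 0]) / sum(abs(d))
  }
}

#' Typed no-score refusal
#'
#' Returned (not thrown) when a gate forbids computing a predictive score,
#' so that report generation can proceed with the clinical sections intact.
#'
#' @param reason Gate that failed: `"TOO_SHORT"`, `"TOO_NOISY"` or
#'   `"FEATURES_UNAVAILABLE"`.
#' @param detail Human-readable sentence for the report.
#' @return An object of class `"sa_no_score"`.
#' @export
sa_no_score <- function(reason, detail = NULL) {
  structure(list(reason = reason, detail = detail %||% reason),
            class = "sa_no_score")
}

#' @export
print.sa_no_score <- function(x, ...) {
  cat("<sa_no_score>", x$reason, "-", x$detail, "\n")
  invisible(x)
}

default_metric_params <- function() {
  list(dfa_scales = 4:16, m = 2, r = 0.15, fuzzy_power = 2,
       mse_max_scale = 10, powerlaw_f_max = 0.04, powerlaw_n_bins = 20)
}

#' Compute the full HRV panel
#'
#' Runs every panel metric on the valid-flag-masked series, recording `NA`
#' plus a reason for any metric that cannot be computed. Refuses with a
#' typed [sa_no_score()] object - not an error - when the quality verdict is
#' not `"OK"`, so the no-score report pathway needs no exception handling.
#'
#' @param series A cleaned [rr_series()].
#' @param respiratory_rate_bpm Respiratory rate from the triage vitals
#'   (breaths/min); the panel does not derive it from the ECG.
#' @param quality An `"sa_quality"` report from [assess_quality()].
#' @param params Metric parameters (see `default_metric_params()`); partial
#'   lists are merged over the defaults.
#' @return An object of class `"hrv_panel"`, or an `"sa_no_score"` object.
#' @examples
#' rr <- clean_rr(gen_rr("physiologic", 1500, 800, 30, seed = 7))
#' q <- assess_quality(rr)
#' panel <- compute_panel(rr, respiratory_rate_bpm = 18, quality = q)
#' tidy(panel)
#' @export
compute_panel <- function(series, respiratory_rate_bpm, quality,
                          params = list()) {
  stopifnot(inherits(series, "rr_series"), inherits(quality, "sa_quality"))
  if (quality$verdict != "OK") {
    detail <- switch(quality$verdict,
      TOO_SHORT = sprintf(
        "recording below %g-minute minimum of usable signal (%.1f min usable)",
        quality$thresholds$min_usable_min, quality$usable_duration_min),
      TOO_NOISY = sprintf(
        "excessive noise: only %.0f%% of intervals usable",
        100 * quality$usable_fraction))
    return(sa_no_score(quality$verdict, detail))
  }
  p <- utils::modifyList(default_metric_params(), params)
  nc <- list()
  grab <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) {
      nc[[name]] <<- conditionMessage(e)
      NA_real_
    })
    if (length(v) == 1 && is.na(v) && !name %in% names(nc)) {
      nc[[name]] <<- "not computable on this series"
    }
    v
  }
  mse <- tryCatch(
    multiscale_entropy(series, p$mse_max_scale, p$m, p$r),
    error = function(e) {
      nc[["mse"]] <<- conditionMessage(e)
      list(curve = tibble::tibble(scale = integer(), sample_entropy = numeric()),
           summary = NA_real_)
    })
  pl <- tryCatch(
    powerlaw_fit(series, f_max = p$powerlaw_f_max, n_bins = p$powerlaw_n_bins),
    error = function(e) {
      nc[["powerlaw"]] <<- conditionMessage(e)
      list(slope = NA_real_, r2 = NA_real_)
    })
  structure(
    list(
      dfa_alpha1 = grab("dfa_alpha1", dfa_alpha1(series, p$dfa_scales)),
      mse_curve = mse$curve,
      mse_summary = mse$summary,
      fuzzy_entropy = grab("fuzzy_entropy",
                           fuzzy_entropy(series, p$m, p$r, p$fuzzy_power)),
      mean_rr_ms = grab("mean_rr_ms", mean_rr(series)),
      powerlaw_slope = pl$slope,
      powerlaw_gof_r2 = pl$r2,
      asymmetry_index_pct = grab("asymmetry_index_pct",
                                 asymmetry_index(series, "porta")),
      guzik_index_pct = grab("guzik_index_pct",
                             asymmetry_index(series, "guzik")),
      respiratory_rate_bpm = as.numeric(respiratory_rate_bpm),
      n_valid_rr = sum(series$valid),
      not_computable = nc,
      params = p
    ),
    class = "hrv_panel"
  )
}

#' @export
print.hrv_panel <- function(x, ...) {
  cat("<hrv_panel>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy an HRV panel into a metric table
#'
#' @param x An `"hrv_panel"`.
#' @param ... Unused.
#' @return A tibble with columns `metric` and `value`.
#' @export
#' @method tidy hrv_panel
tidy.hrv_panel <- function(x, ...) {
  tibble::tibble(
    metric = c("dfa_alpha1", "mse_summary", "fuzzy_entropy", "mean_rr_ms",
               "powerlaw_slope", "powerlaw_gof_r2", "asymmetry_index_pct",
               "guzik_index_pct", "respiratory_rate_bpm", "n_valid_rr"),
    value = c(x$dfa_alpha1, x$mse_summary, x$fuzzy_entropy, x$mean_rr_ms,
              x$powerlaw_slope, x$powerlaw_gof_r2, x$asymmetry_index_pct,
              x$guzik_index_pct, x$respiratory_rate_bpm, x$n_valid_rr)
  )
}
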