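#' Detect R-peaks on a lead-II ECG
#'
#' A Pan-Tompkins-family detector: zero-phase band-pass (5-25 Hz Butterworth),
#' squared derivative, centred moving-window integration, segment-wise
#' adaptive thresholding, then refinement of each fiducial to the local
#' maximum of the raw waveform within +/- 40 ms (ties broken to the earliest
#' sample). A 200 ms refractory period is enforced; where two candidates
#' collide the one with the stronger integrated response survives.
#'
#' @param ecg An [ecg_recording()] of at least 10 s at >= 100 Hz.
#' @param band Pass band of the QRS filter, Hz.
#' @param refractory_s Minimum separation between reported beats, seconds.
#' @param threshold_frac Fraction of the segment-wise 99th percentile of the
#'   integrated signal used as detection threshold.
#' @return Numeric vector of strictly increasing beat times in seconds
#'   (relative to the recording clock).
#' @examples
#' sim <- gen_ecg(gen_rr("white", 30, 800, 20, seed = 1), 250, seed = 1)
#' beats <- detect_r_peaks(sim$ecg)
#' length(beats)
#' @export
detect_r_peaks <- function(ecg, band = c(5, 25), refractory_s = 0.2,
                           threshold_frac = 0.25) {
  stopifnot(inherits(ecg, "ecg_recording"))
  fs <- ecg$sampling_rate_hz
  x <- ecg$samples_mv
  if (duration_s(ecg) < 10) {
    sa_abort("Recording shorter than 10 s; too short for beat detection.",
             "hrvrisk_too_short")
  }
  if (sd(x) == 0) {
    sa_abort("no beats detectable: flat (zero-variance) signal.",
             "hrvrisk_no_beats")
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  d2 <- c(0, diff(xf))^2
  win <- max(3L, as.integer(round(0.15 * fs)))
  integ <- as.numeric(stats::filter(d2, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0

  # segment-wise threshold guards against slow amplitude drift; the global
  # floor keeps silent segments from detecting noise
  seg_len <- as.integer(round(8 * fs))
  seg <- ceiling(seq_along(integ) / seg_len)
  seg_q <- tapply(integ, seg, quantile, probs = 0.99, names = FALSE)
  thr <- threshold_frac * pmax(seg_q[seg], 0.1 * median(seg_q))

  above <- as.vector(integ > thr)
  if (!any(above)) {
    sa_abort("no beats detectable: no suprathreshold activity.",
             "hrvrisk_no_beats")
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  fiducials <- purrr::map_int(which(runs$values), function(k) {
    i <- starts[k]:ends[k]
    as.integer(i[which.max(integ[i])])
  })

  # refine to the raw-waveform local maximum within +/- 40 ms
  half <- as.integer(round(0.04 * fs))
  peaks <- vapply(fiducials, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    w <- lo:hi
    as.integer(w[which.max(x[w])])       # which.max: earliest of equal maxima
  }, integer(1))
  strength <- integ[fiducials]

  o <- order(peaks)
  peaks <- peaks[o]; strength <- strength[o]
  keep_dup <- !duplicated(peaks)
  peaks <- peaks[keep_dup]; strength <- strength[keep_dup]

  # refractory: greedy pass keeping the stronger of colliding candidates
  min_gap <- refractory_s * fs
  keep <- rep(TRUE, length(peaks))
  last <- 1L
  for (i in seq_along(peaks)[-1]) {
    if (peaks[i] - peaks[last] < min_gap) {
      if (strength[i] > strength[last]) {
        keep[last] <- FALSE
        last <- i
      } else {
        keep[i] <- FALSE
      }
    } else {
      last <- i
    }
  }
  peaks <- peaks[keep]
  if (length(peaks) == 0) {
    sa_abort("no beats detectable.", "hrvrisk_no_beats")
  }
  ecg$start_offset_s + (peaks - 1) / fs
}

#' Build an RR series from beat times
#'
#' @param beat_times_s Strictly increasing beat times in seconds (>= 2 beats).
#' @return An [rr_series()] with every interval flagged valid.
#' @export
build_rr <- function(beat_times_s) {
  beat_times_s <- as.numeric(beat_times_s)
  if (length(beat_times_s) < 2) {
    sa_abort("At least 2 beats are needed to form RR intervals.",
             "hrvrisk_too_few_beats")
  }
  rr <- diff(beat_times_s) * 1000
  new_rr_series(beat_times_s, rr, rep(TRUE, length(rr)))
}

#' Flag physiologically implausible and ectopic-like RR intervals
#'
#' Two rules, applied in one sequential pass: (1) intervals outside
#' `range_ms` are invalid; (2) an interval deviating from the median of the
#' (up to) five preceding valid intervals by more than `jump_frac` is invalid.
#' Flags are the only mutation - nothing is deleted - and intervals already
#' flagged invalid stay invalid, which makes the operation idempotent.
#'
#' @param series An [rr_series()].
#' @param range_ms Plausible RR range in ms (default 300-2000).
#' @param jump_frac Maximum tolerated relative deviation from the local
#'   median (default 0.20).
#' @return The series with updated `valid` flags.
#' @export
clean_rr <- function(series, range_ms = c(300, 2000), jump_frac = 0.20) {
  stopifnot(inherits(series, "rr_series"))
  rr <- series$rr_ms
  valid <- series$valid
  valid <- valid & rr >= range_ms[1] & rr <= range_ms[2]
  for (i in seq_along(rr)) {
    if (!valid[i]) next
    prev <- which(valid[seq_len(i - 1)])
    if (length(prev) == 0) next
    ref <- median(rr[tail(prev, 5)])
    if (abs(rr[i] - ref) > jump_frac * ref) valid[i] <- FALSE
  }
  series$valid <- valid
  series
}

#' Quality gate for HRV analysis
#'
#' Decides whether a predictive score may be produced. The floor is 15
#' minutes of *usable* recording - the sum of valid RR intervals, not
#' wall-clock time - because the minimum-duration rule exists to guarantee
#' that HRV analysis is possible. A recording clearing the floor is still
#' rejected as too noisy when fewer than `min_usable_fraction` of its
#' intervals are valid.
#'
#' @param series A cleaned [rr_series()] (see [clean_rr()]).
#' @param recording_duration_min Wall-clock duration in minutes (reported in
#'   the quality section; defaults to the series span).
#' @param min_usable_min Usable-duration floor in minutes.
#' @param min_usable_fraction Minimum fraction of valid intervals.
#' @param ... Passed to [rhythm_screen()].
#' @return An object of class `"sa_quality"` with fields
#'   `usable_duration_min`, `usable_fraction`, `verdict` (`"OK"`,
#'   `"TOO_SHORT"` or `"TOO_NOISY"`) and `rhythm_flag`.
#' @export
assess_quality <- function(series, recording_duration_min = NULL,
                           min_usable_min = 15, min_usable_fraction = 0.80,
                           ...) {
  stopifnot(inherits(series, "rr_series"))
  if (is.null(recording_duration_min)) {
    recording_duration_min <- duration_s(series) / 60
  }
  usable_min <- sum(series$rr_ms[series$valid]) / 60000
  frac <- mean(series$valid)
  verdict <- if (usable_min < min_usable_min) {
    "TOO_SHORT"
  } else if (frac < min_usable_fraction) {
    "TOO_NOISY"
  } else {
    "OK"
  }
  structure(
    list(
      usable_duration_min = usable_min,
      usable_fraction = frac,
      verdict = verdict,
      rhythm_flag = rhythm_screen(series, ...),
      recording_duration_min = recording_duration_min,
      thresholds = list(min_usable_min = min_usable_min,
                        min_usable_fraction = min_usable_fraction)
    ),
    class = "sa_quality"
  )
}

#' @export
print.sa_quality <- function(x, ...) {
  cat(sprintf(
    "<sa_quality> %s: %.1f min usable (%.0f%% of intervals), rhythm %s\n",
    x$verdict, x$usable_duration_min, 100 * x$usable_fraction, x$rhythm_flag))
  invisible(x)
}

#' Screen the RR series for non-sinus-like irregularity
#'
#' A coarse irregularity flag - a screen, not a diagnosis - standing in for
#' the manual rhythm exclusion (atrial fibrillation, paced and other
#' non-sinus rhythms preclude HRV analysis). Fires when the coefficient of
#' variation of valid RR intervals exceeds `cv_threshold`, or when the
#' fraction of successive valid-pair differences above 50 ms exceeds
#' `big_delta_frac` (an AF-like successive-difference signature).
#'
#' @param series An [rr_series()] with >= 60 valid intervals (fewer returns
#'   `"SINUS_LIKE"` with a warning, as the screen is then uninformative).
#' @param cv_threshold Coefficient-of-variation threshold.
#' @param big_delta_frac Threshold on the fraction of successive differences
#'   exceeding 50 ms.
#' @return `"SINUS_LIKE"` or `"IRREGULAR_SUSPECT"`.
#' @export
rhythm_screen <- function(series, cv_threshold = 0.18, big_delta_frac = 0.6) {
  stopifnot(inherits(series, "rr_series"))
  rr <- series$rr_ms[series$valid]
  if (length(rr) < 60) {
    warn("Fewer than 60 valid RR intervals: rhythm screen unassessed, returning SINUS_LIKE.",
         class = "hrvrisk_rhythm_unassessed")
    return("SINUS_LIKE")
  }
  cv <- sd(rr) / mean(rr)
  ok_pair <- series$valid[-1] & series$valid[-length(series$valid)]
  deltas <- abs(diff(series$rr_ms))[ok_pair]
  frac_big <- if (length(deltas)) mean(deltas > 50) else 0
  if (cv > cv_threshold || frac_big > big_delta_frac) {
    "IRREGULAR_SUSPECT"
  } else {
    "SINUS_LIKE"
  }
}

#' Export beat times as WFDB-style annotation text
#'
#' One line per beat: sample index (0-based) and the symbol `N`.
#'
#' @param beat_times_s Beat times in seconds.
#' @param sampling_rate_hz Sampling rate used to convert times to indices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beat_annotations <- function(beat_times_s, sampling_rate_hz, path) {
  idx <- as.integer(round(beat_times_s * sampling_rate_hz))
  writeLines(sprintf("%d N", idx), path)
  invisible(path)
}
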