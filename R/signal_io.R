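#' ECG recording and RR-interval series containers
#'
#' `ecg_recording()` wraps a sampled single-lead waveform; `rr_series()` wraps
#' an interbeat (RR) interval sequence. These are the two substrates of the
#' pipeline: the detector turns a recording into beat times, [build_rr()] turns
#' beat times into an `rr_series`, and every HRV metric consumes an
#' `rr_series`. Canonical units throughout the package: millivolts for
#' samples, seconds for beat times, milliseconds for RR intervals.
#'
#' An `rr_series` keeps three aligned pieces: `beat_times_s` (strictly
#' increasing, length `n`), `rr_ms` (length `n - 1`, all positive) and a
#' logical `valid` flag per interval. Cleaning ([clean_rr()]) only ever flips
#' flags; no interval is deleted, so metrics can select contiguous valid runs.
#'
#' @param samples_mv Numeric vector of samples in millivolts; must be finite.
#' @param sampling_rate_hz Sampling rate in Hz (>= 100).
#' @param lead_label Lead name; the pipeline expects `"II"`.
#' @param start_offset_s Offset of the first sample from the reference clock.
#' @return `ecg_recording()` returns an object of class `"ecg_recording"`;
#'   `rr_series()` an object of class `"rr_series"`.
#' @examples
#' rec <- ecg_recording(sin(2 * pi * seq(0, 10, by = 1 / 250)), 250)
#' rec
#' rr <- rr_series(c(800, 810, 790))
#' rr$beat_times_s
#' @export
ecg_recording <- function(samples_mv, sampling_rate_hz, lead_label = "II",
                          start_offset_s = 0) {
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz < 100) {
    sa_abort("`sampling_rate_hz` must be a single finite number >= 100.",
             "hrvrisk_bad_rate")
  }
  samples_mv <- as.numeric(samples_mv)
  if (length(samples_mv) == 0) {
    sa_abort("ECG signal is empty.", "hrvrisk_empty_signal")
  }
  n_bad <- sum(!is.finite(samples_mv))
  if (n_bad > 0) {
    sa_abort(sprintf("non-finite sample: %d non-finite value(s) in ECG signal.",
                     n_bad),
             "hrvrisk_nonfinite_sample")
  }
  structure(
    list(
      lead_label = as.character(lead_label),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      samples_mv = samples_mv,
      start_offset_s = as.numeric(start_offset_s)
    ),
    class = "ecg_recording"
  )
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> lead %s, %.6g Hz, %d samples (%.1f s)\n",
              x$lead_label, x$sampling_rate_hz, length(x$samples_mv),
              duration_s(x)))
  invisible(x)
}

#' Duration of a recording or RR series
#'
#' For an `ecg_recording`, `count(samples) / sampling_rate`, exactly. For an
#' `rr_series`, the span of its beat times in seconds.
#'
#' @param x An `ecg_recording` or `rr_series`.
#' @return Duration in seconds.
#' @export
duration_s <- function(x) UseMethod("duration_s")

#' @export
duration_s.ecg_recording <- function(x) {
  length(x$samples_mv) / x$sampling_rate_hz
}

#' @export
duration_s.rr_series <- function(x) {
  if (length(x$beat_times_s) == 0) return(0)
  max(x$beat_times_s) - min(x$beat_times_s)
}

#' @rdname ecg_recording
#' @param rr_ms Positive RR intervals in milliseconds.
#' @param valid Logical validity flag per interval (recycled).
#' @param start_time_s Time of the first beat; beat times are the cumulative
#'   sum of the intervals from this origin.
#' @export
rr_series <- function(rr_ms, valid = TRUE, start_time_s = 0) {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) < 1 || any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    sa_abort("RR intervals must be a non-empty vector of positive finite ms.",
             "hrvrisk_bad_rr")
  }
  beat_times_s <- start_time_s + c(0, cumsum(rr_ms) / 1000)
  new_rr_series(beat_times_s, rr_ms, rep_len(as.logical(valid), length(rr_ms)))
}

# Low-level constructor: checks the beat-time / interval consistency invariant.
new_rr_series <- function(beat_times_s, rr_ms, valid) {
  stopifnot(length(rr_ms) == length(beat_times_s) - 1,
            length(valid) == length(rr_ms))
  if (any(diff(beat_times_s) <= 0)) {
    sa_abort("Beat times must be strictly increasing.", "hrvrisk_bad_beats")
  }
  if (max(abs(diff(beat_times_s) * 1000 - rr_ms)) > 1e-9 * max(1, max(rr_ms))) {
    sa_abort("RR intervals inconsistent with beat times.", "hrvrisk_bad_rr")
  }
  structure(
    list(beat_times_s = as.numeric(beat_times_s), rr_ms = as.numeric(rr_ms),
         valid = as.logical(valid)),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %d intervals, %.1f s, mean RR %.1f ms, %.1f%% valid\n",
    length(x$rr_ms), duration_s(x), mean(x$rr_ms), 100 * mean(x$valid)))
  invisible(x)
}

#' @export
#' @method as_tibble rr_series
as_tibble.rr_series <- function(x, ...) {
  tibble::tibble(
    onset_s = x$beat_times_s[-length(x$beat_times_s)],
    rr_ms = x$rr_ms,
    valid = x$valid
  )
}

#' @export
#' @method as_tibble ecg_recording
as_tibble.ecg_recording <- function(x, ...) {
  tibble::tibble(
    time_s = x$start_offset_s +
      (seq_along(x$samples_mv) - 1) / x$sampling_rate_hz,
    ecg_mv = x$samples_mv
  )
}

#' Read and write ECG waveforms as CSV
#'
#' The CSV dialect is deliberately rigid: comma-separated, an optional single
#' header row (auto-detected by a non-numeric first row), one numeric column
#' per channel. The sampling rate is not stored in the file and must be
#' supplied. Any non-finite value in the chosen column is a hard load failure
#' (the pipeline never analyses gap-filled waveforms).
#'
#' @param path File path.
#' @param sampling_rate_hz Sampling rate of the stored samples, in Hz.
#' @param column Column name or index holding the waveform (default first).
#' @inheritParams ecg_recording
#' @return `read_ecg_csv()` returns an [ecg_recording()]; `write_ecg_csv()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' rec <- ecg_recording(rnorm(500), 250)
#' write_ecg_csv(rec, f)
#' rec2 <- read_ecg_csv(f, 250)
#' identical(rec$samples_mv, rec2$samples_mv)
#' @export
read_ecg_csv <- function(path, sampling_rate_hz, column = 1,
                         lead_label = "II") {
  if (!file.exists(path)) {
    sa_abort(sprintf("File not found: %s", path), "hrvrisk_missing_file")
  }
  first <- readLines(path, n = 1L)
  first_fields <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first_fields))))
  df <- read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (is.character(column)) {
    if (!column %in% names(df)) {
      sa_abort(sprintf("Column '%s' not present in %s.", column, path),
               "hrvrisk_bad_column")
    }
    col <- df[[column]]
  } else {
    if (column < 1 || column > ncol(df)) {
      sa_abort(sprintf("Column index %d out of range.", column),
               "hrvrisk_bad_column")
    }
    col <- df[[column]]
  }
  if (!is.numeric(col)) {
    sa_abort("Chosen CSV column is not numeric.", "hrvrisk_bad_column")
  }
  ecg_recording(col, sampling_rate_hz, lead_label = lead_label)
}

#' @rdname read_ecg_csv
#' @param recording An [ecg_recording()].
#' @export
write_ecg_csv <- function(recording, path) {
  stopifnot(inherits(recording, "ecg_recording"))
  # %.17g keeps doubles bit-exact through the text round trip
  writeLines(c("ecg_mv", formatC(recording$samples_mv, format = "g",
                                 digits = 17)), path)
  invisible(path)
}

#' Read and write RR-interval text files
#'
#' One RR interval in milliseconds per line; lines starting with `#` are
#' comments. Beat times are reconstructed by cumulative summation from zero.
#' Writing stores three decimals (microsecond resolution), which the read
#' side reproduces exactly.
#'
#' @param path File path.
#' @return `read_rr_text()` returns an [rr_series()] with all intervals
#'   flagged valid; `write_rr_text()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_rr_text(rr_series(c(800, 810, 790)), f)
#' read_rr_text(f)$beat_times_s
#' @export
read_rr_text <- function(path) {
  if (!file.exists(path)) {
    sa_abort(sprintf("File not found: %s", path), "hrvrisk_missing_file")
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  line_no <- which(keep)
  bad <- which(!is.finite(vals) | vals <= 0)
  if (length(vals) == 0) {
    sa_abort("RR file contains no intervals.", "hrvrisk_empty_signal")
  }
  if (length(bad) > 0) {
    sa_abort(sprintf("Non-positive or unreadable RR interval at line %d.",
                     line_no[bad[1]]),
             "hrvrisk_bad_rr")
  }
  rr_series(vals)
}

#' @rdname read_rr_text
#' @param series An [rr_series()].
#' @export
write_rr_text <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  writeLines(c("# RR intervals (ms), one per line",
               sprintf("%.3f", series$rr_ms)), path)
  invisible(path)
}

#' Read a standard-format waveform record (WFDB or EDF)
#'
#' Minimal, read-only support for the two waveform interchange formats the
#' pipeline meets in practice: WFDB (`.hea` + format-16 `.dat`) and EDF.
#' The lead labelled `"II"` (case-insensitive) is selected unless `channel`
#' overrides; samples are converted to millivolts using the record's stated
#' gain (WFDB) or physical calibration and dimension (EDF).
#'
#' @param path Record path: the `.hea` file (or its stem) for WFDB, the
#'   `.edf` file for EDF.
#' @param format `"wfdb"` or `"edf"`.
#' @param channel Optional channel index overriding lead-II selection.
#' @return An [ecg_recording()].
#' @export
read_ecg_record <- function(path, format = c("wfdb", "edf"), channel = NULL) {
  format <- match.arg(format)
  switch(format,
         wfdb = read_wfdb_record(path, channel),
         edf = read_edf_record(path, channel))
}

pick_lead_ii <- function(labels, channel, path) {
  if (!is.null(channel)) {
    if (channel < 1 || channel > length(labels)) {
      sa_abort("Channel override out of range.", "hrvrisk_bad_column")
    }
    return(channel)
  }
  hit <- which(toupper(trimws(labels)) %in% c("II", "LEAD II", "MLII"))
  if (length(hit) == 0) {
    sa_abort(sprintf("lead II not found (channels: %s); pass `channel`.",
                     paste(trimws(labels), collapse = ", ")),
             "hrvrisk_no_lead_ii")
  }
  hit[1]
}

unit_to_mv <- function(unit) {
  switch(toupper(trimws(unit)),
         "MV" = 1, "UV" = 1e-3, "V" = 1e3,
         sa_abort(sprintf("Unsupported amplitude unit '%s'.", unit),
                  "hrvrisk_bad_units"))
}

read_wfdb_record <- function(path, channel = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) {
    sa_abort(sprintf("WFDB header not found: %s", hea), "hrvrisk_missing_file")
  }
  lines <- readLines(hea)
  lines <- lines[!grepl("^\\s*#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  sig <- lines[1 + seq_len(nsig)]
  parse_sig <- function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    gain_field <- f[3]
    units <- "mV"
    if (grepl("/", gain_field)) {
      units <- sub("^[^/]*/", "", gain_field)
      gain_field <- sub("/.*$", "", gain_field)
    }
    baseline <- 0
    if (grepl("\\(", gain_field)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
      gain_field <- sub("\\(.*$", "", gain_field)
    }
    gain <- as.numeric(gain_field)
    if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default gain
    list(file = f[1], format = f[2], gain = gain, baseline = baseline,
         units = units, label = if (length(f) >= 9)
           paste(f[9:length(f)], collapse = " ") else paste0("ch", f[1]))
  }
  sigs <- lapply(sig, parse_sig)
  if (any(vapply(sigs, function(s) s$format, "") != "16")) {
    sa_abort("Only WFDB format 16 is supported.", "hrvrisk_bad_format")
  }
  labels <- vapply(sigs, function(s) s$label, "")
  idx <- pick_lead_ii(labels, channel, path)
  dat <- file.path(dirname(hea), sigs[[1]]$file)
  if (!file.exists(dat)) {
    sa_abort(sprintf("WFDB data file not found: %s", dat),
             "hrvrisk_missing_file")
  }
  raw <- readBin(dat, "integer", n = file.size(dat) / 2, size = 2,
                 signed = TRUE, endian = "little")
  nsamp <- length(raw) %/% nsig
  adc <- matrix(raw[seq_len(nsamp * nsig)], nrow = nsig)[idx, ]
  s <- sigs[[idx]]
  mv <- (adc - s$baseline) / s$gain * unit_to_mv(s$units)
  ecg_recording(mv, fs, lead_label = trimws(labels[idx]))
}

read_edf_record <- function(path, channel = NULL) {
  if (!file.exists(path)) {
    sa_abort(sprintf("EDF file not found: %s", path), "hrvrisk_missing_file")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)         # version, patient, recording, date, time
  rd(8)                                        # header bytes
  rd(44)                                       # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16)
  fld(80)                                      # transducer
  dims <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                                      # prefiltering
  spr <- as.integer(fld(8))                    # samples per record
  fld(32)                                      # reserved
  idx <- pick_lead_ii(labels, channel, path)
  out <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                   endian = "little")
      if (s == idx) out[[r]] <- v
    }
  }
  d <- unlist(out)
  phys <- phys_min[idx] +
    (d - dig_min[idx]) * (phys_max[idx] - phys_min[idx]) /
      (dig_max[idx] - dig_min[idx])
  fs <- spr[idx] / rec_dur
  ecg_recording(phys * unit_to_mv(dims[idx]), fs,
                lead_label = trimws(labels[idx]))
}

#' Write synthetic waveform records for interoperability fixtures
#'
#' Fixture writers producing minimal, valid WFDB (format 16) and EDF files
#' from an [ecg_recording()]. They exist so the standard-format readers can be
#' exercised round-trip on synthetic records; they are not general-purpose
#' exporters (single data segment, one or more identical-rate channels).
#'
#' @param recording An [ecg_recording()].
#' @param stem Output path stem (without extension).
#' @param gain ADC units per millivolt for WFDB quantization.
#' @param extra_labels Optional labels of additional (zero-filled) channels
#'   written before the recording's own channel.
#' @return The header/file path, invisibly.
#' @keywords internal
#' @export
write_wfdb_record <- function(recording, stem, gain = 200,
                              extra_labels = character()) {
  labels <- c(extra_labels, recording$lead_label)
  nsig <- length(labels)
  n <- length(recording$samples_mv)
  adc <- as.integer(round(recording$samples_mv * gain))
  adc <- pmax(pmin(adc, 32767L), -32768L)
  mat <- matrix(0L, nrow = nsig, ncol = n)
  mat[nsig, ] <- adc
  dat <- paste0(basename(stem), ".dat")
  hea <- paste0(stem, ".hea")
  header <- c(
    sprintf("%s %d %.10g %d", basename(stem), nsig,
            recording$sampling_rate_hz, n),
    sprintf("%s 16 %g/mV 16 0 0 0 0 %s", dat, gain, labels)
  )
  writeLines(header, hea)
  writeBin(as.integer(mat), file.path(dirname(stem), dat), size = 2,
           endian = "little")
  invisible(hea)
}

#' @rdname write_wfdb_record
#' @export
write_edf_record <- function(recording, stem, extra_labels = character()) {
  path <- paste0(stem, ".edf")
  labels <- c(extra_labels, recording$lead_label)
  ns <- length(labels)
  fs <- recording$sampling_rate_hz
  x <- recording$samples_mv
  rec_dur <- 1
  spr <- as.integer(round(fs * rec_dur))
  n_rec <- ceiling(length(x) / spr)
  x <- c(x, rep(0, n_rec * spr - length(x)))
  phys_min <- min(x) - 1e-6; phys_max <- max(x) + 1e-6
  dig_min <- -32768; dig_max <- 32767
  d <- as.integer(round((x - phys_min) / (phys_max - phys_min) *
                          (dig_max - dig_min) + dig_min))
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(s, w) {
    s <- sprintf("%-*s", w, s)
    writeBin(charToRaw(substr(s, 1, w)), con)
  }
  wf("0", 8); wf("X", 80); wf("X", 80)
  wf("01.01.26", 8); wf("00.00.00", 8)
  wf(sprintf("%d", 256 * (1 + ns)), 8); wf("", 44)
  wf(sprintf("%d", n_rec), 8); wf(sprintf("%g", rec_dur), 8)
  wf(sprintf("%d", ns), 4)
  for (l in labels) wf(l, 16)
  for (i in seq_len(ns)) wf("synthetic", 80)
  for (i in seq_len(ns)) wf("mV", 8)
  for (i in seq_len(ns)) wf(sprintf("%.6g", phys_min), 8)
  for (i in seq_len(ns)) wf(sprintf("%.6g", phys_max), 8)
  for (i in seq_len(ns)) wf(sprintf("%d", dig_min), 8)
  for (i in seq_len(ns)) wf(sprintf("%d", dig_max), 8)
  for (i in seq_len(ns)) wf("", 80)
  for (i in seq_len(ns)) wf(sprintf("%d", spr), 8)
  for (i in seq_len(ns)) wf("", 32)
  zero <- rep(0L, spr)
  for (r in seq_len(n_rec)) {
    seg <- d[((r - 1) * spr + 1):(r * spr)]
    for (s in seq_len(ns)) {
      writeBin(if (s == ns) seg else zero, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
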