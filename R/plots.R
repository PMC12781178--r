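#' Plot methods
#'
#' `autoplot()` methods for the pipeline's objects: the waveform with
#' detected beats, the RR tachogram with validity flags, and the multiscale
#' entropy curve of a panel. `plot_poincare()` draws the Poincare plot
#' underlying the asymmetry indices.
#'
#' @param object An `ecg_recording`, `rr_series` or `hrv_panel`.
#' @param beats Optional beat times (s) overlaid on the waveform.
#' @param ... Unused.
#' @return A ggplot object.
#' @name hrvrisk-plots
NULL

#' @rdname hrvrisk-plots
#' @export
#' @method autoplot ecg_recording
autoplot.ecg_recording <- function(object, beats = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$ecg_mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "lead II (mV)")
  if (!is.null(beats)) {
    p <- p + ggplot2::geom_vline(xintercept = beats, colour = "red",
                                 alpha = 0.3, linetype = 2)
  }
  p
}

#' @rdname hrvrisk-plots
#' @export
#' @method autoplot rr_series
autoplot.rr_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$onset_s, .data$rr_ms,
                               colour = .data$valid)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "red")) +
    ggplot2::labs(x = "time (s)", y = "RR (ms)", colour = "valid")
}

#' @rdname hrvrisk-plots
#' @export
#' @method autoplot hrv_panel
autoplot.hrv_panel <- function(object, ...) {
  ggplot2::ggplot(object$mse_curve,
                  ggplot2::aes(.data$scale, .data$sample_entropy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "coarse-graining scale (beats)",
                  y = "sample entropy (nats)",
                  title = "Multiscale entropy")
}

#' @rdname hrvrisk-plots
#' @param series An [rr_series()].
#' @export
plot_poincare <- function(series, ...) {
  stopifnot(inherits(series, "rr_series"))
  n <- length(series$rr_ms)
  ok <- series$valid[-n] & series$valid[-1]
  df <- tibble::tibble(rr_i = series$rr_ms[-n][ok],
                       rr_next = series$rr_ms[-1][ok])
  ggplot2::ggplot(df, ggplot2::aes(.data$rr_i, .data$rr_next)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(RR[i] ~ "(ms)"),
                  y = expression(RR[i + 1] ~ "(ms)"))
}
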