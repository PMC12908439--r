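#' Uniformly sampled signal
#'
#' Container for a uniformly sampled real-valued time series, the basic input
#' of the Prony pipeline. Samples are implicitly located at times
#' `t_k = t0 + k / sampling_rate`, `k = 0, 1, ...`.
#'
#' @param samples Numeric vector of at least 4 finite values, in signal units
#'   (e.g. mmHg for pressure, uL for volume).
#' @param sampling_rate Sampling rate in Hz; must be positive.
#' @param label Short label for the signal (e.g. `"pressure"`).
#' @param t0 Time of the first sample in seconds.
#'
#' @return An object of class `prony_signal`: a list with elements `samples`,
#'   `sampling_rate`, `label` and `t0`.
#' @examples
#' s <- prony_signal(cos(2 * pi * 7 * seq(0, 0.999, by = 0.001)), 1000,
#'                   label = "pressure")
#' length(s$samples)
#' @export
prony_signal <- function(samples, sampling_rate, label = "signal", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 4L)
    stop("a signal needs at least 4 samples, got ", length(samples))
  if (!all(is.finite(samples)))
    stop("all samples must be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("'sampling_rate' must be a single positive number (Hz)")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         label = as.character(label)[1L], t0 = as.numeric(t0)[1L]),
    class = "prony_signal"
  )
}

#' Coerce to a signal object
#'
#' Numeric vectors are wrapped with the supplied sampling rate (default 1 Hz,
#' i.e. sample-index time); `prony_signal` objects pass through unchanged.
#'
#' @param x A `prony_signal` or numeric vector.
#' @param sampling_rate Sampling rate used when `x` is a bare vector.
#' @param label Label used when `x` is a bare vector.
#' @return A `prony_signal`.
#' @export
as_prony_signal <- function(x, sampling_rate = 1, label = "signal") {
  if (inherits(x, "prony_signal")) return(x)
  prony_signal(x, sampling_rate, label = label)
}

#' Sample times of a signal
#'
#' @param x A `prony_signal`.
#' @return Numeric vector of times in seconds, one per sample.
#' @export
signal_times <- function(x) {
  x <- as_prony_signal(x)
  x$t0 + (seq_along(x$samples) - 1) / x$sampling_rate
}

#' @export
print.prony_signal <- function(x, ...) {
  cat(sprintf("<prony_signal '%s': %d samples @ %g Hz (%.4g s), range [%.4g, %.4g]>\n",
              x$label, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              min(x$samples), max(x$samples)))
  invisible(x)
}
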