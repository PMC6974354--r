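# Noise estimation and calcium-transient peak detection.

#' Estimate the noise SD of a dF/F0 trace
#'
#' The trace is high-pass filtered at 0.6 Hz (9th order, zero-phase) to
#' strip indicator transients, and the standard deviation of the residual
#' is returned. Detection thresholds are expressed as multiples of this SD.
#'
#' @param dff a `trace` with `kind = "dff"`.
#' @param cutoff high-pass cutoff in Hz.
#' @param order filter order.
#' @return noise SD in dF/F0 units.
#' @export
estimate_noise_sd <- function(dff, cutoff = 0.6, order = 9) {
  if (!inherits(dff, "trace")) stop("dff must be a trace")
  if (dff$kind != "dff") stop("estimate_noise_sd expects a dF/F0 trace")
  if (length(dff$values) < 3 * (order + 1))
    stop("trace shorter than 3 filter lengths")
  # remove the mean first: the high-pass kills DC exactly, so this only
  # suppresses the numerical startup transient of the IIR recursion
  x <- dff$values - mean(dff$values)
  stats::sd(highpass_butter(x, dff$fs, cutoff = cutoff, order = order))
}

# Strict local maxima; a plateau contributes its left-most sample provided
# the signal falls after it. Endpoints are never peaks.
find_local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  starts <- cumsum(r$lengths) - r$lengths + 1L
  inner <- 2:(k - 1)
  up <- r$values[inner] > r$values[inner - 1]
  down <- r$values[inner] > r$values[inner + 1]
  starts[inner][up & down]
}

#' Detect calcium-transient peaks
#'
#' Events are strict local maxima of the dF/F0 trace whose height exceeds
#' `multiplier` times the noise SD (default multiplier 2.8). Each event's
#' amplitude is the peak dF/F0 minus the minimum over a backward window of
#' `window_s` seconds ending at (and including) the peak sample; detection
#' height and amplitude are deliberately distinct quantities. Amplitudes are
#' normalised to the maximum amplitude in the session for that compartment;
#' pass `norm_max` to normalise against a session-wide maximum when a
#' session spans several traces.
#'
#' @param dff a `trace` with `kind = "dff"`.
#' @param noise_sd noise SD in dF/F0 units; computed via
#'   [estimate_noise_sd()] when `NULL`.
#' @param multiplier detection threshold in noise-SD units (default 2.8).
#' @param window_s backward window for the local-minimum amplitude
#'   reference, in seconds (default 2); truncated at the trace start.
#' @param norm_max optional amplitude used for normalisation instead of the
#'   within-trace maximum.
#' @return object of class `"event_series"`: data.frame `events` with
#'   columns `peak_time`, `peak_index`, `value`, `amplitude`,
#'   `norm_amplitude`, plus the trace metadata, `noise_sd` and `multiplier`.
#' @export
detect_events <- function(dff, noise_sd = NULL, multiplier = 2.8,
                          window_s = 2, norm_max = NULL) {
  if (!inherits(dff, "trace")) stop("dff must be a trace")
  if (dff$kind != "dff") stop("detect_events expects a dF/F0 trace")
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(dff)
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive")
  x <- dff$values
  peaks <- find_local_maxima(x)
  peaks <- peaks[x[peaks] > multiplier * noise_sd]
  w <- floor(window_s * dff$fs)
  amp <- vapply(peaks, function(i) {
    x[i] - min(x[max(1L, i - w):i])
  }, numeric(1))
  tt <- trace_times(dff)
  if (is.null(norm_max)) norm_max <- if (length(amp)) max(amp) else NA_real_
  events <- data.frame(peak_time = tt[peaks], peak_index = peaks,
                       value = x[peaks], amplitude = amp,
                       norm_amplitude = if (length(amp)) amp / norm_max
                                        else numeric(0))
  structure(list(events = events, trace_id = dff$trace_id,
                 neuron_id = dff$neuron_id, compartment = dff$compartment,
                 fs = dff$fs, noise_sd = noise_sd, multiplier = multiplier,
                 norm_max = norm_max),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series '%s'> %d events (threshold %.3g = %.2f x noise SD %.4g)\n",
              x$trace_id, nrow(x$events), x$multiplier * x$noise_sd,
              x$multiplier, x$noise_sd))
  invisible(x)
}

#' Detect events across a set of thresholds
#'
#' Re-runs [detect_events()] for each multiplier (the robustness analysis
#' uses the selected threshold +/- 30%). Event counts are non-increasing in
#' the multiplier by construction.
#'
#' @inheritParams detect_events
#' @param multipliers numeric vector of positive threshold multipliers.
#' @return named list of `event_series`, one per multiplier.
#' @export
threshold_sweep <- function(dff, noise_sd = NULL,
                            multipliers = c(0.7, 1, 1.3) * 2.8,
                            window_s = 2, norm_max = NULL) {
  if (length(multipliers) == 0) stop("multipliers must be non-empty")
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(dff)
  out <- lapply(multipliers, function(m)
    detect_events(dff, noise_sd, multiplier = m, window_s = window_s,
                  norm_max = norm_max))
  names(out) <- format(multipliers)
  out
}
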