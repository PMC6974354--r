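COMPARTMENTS <- c("soma", "pTrunk", "dTrunk", "trunk", "pTuft", "dTuft",
                  "tuft", "tuft_branch")

#' Fluorescence trace for one region of interest
#'
#' The atom of the pipeline: one ROI's fluorescence over time, with its
#' sampling rate, compartment identity and signal kind. `kind = "raw"` holds
#' fluorescence in arbitrary units as extracted from the movie; `kind = "dff"`
#' holds the baseline-normalised change dF/F0 (dimensionless).
#'
#' @param values numeric vector of samples; must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param trace_id identifier for this ROI.
#' @param neuron_id identifier of the neuron the ROI belongs to.
#' @param compartment one of `"soma"`, `"pTrunk"`, `"dTrunk"`, `"trunk"`,
#'   `"pTuft"`, `"dTuft"`, `"tuft"`, `"tuft_branch"`.
#' @param kind `"raw"` or `"dff"`.
#' @return An object of class `"trace"`.
#' @export
new_trace <- function(values, fs, t0 = 0, trace_id = "trace",
                      neuron_id = NA_character_, compartment = "soma",
                      kind = c("raw", "dff")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("trace values must be finite")
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive finite number")
  if (!is.finite(t0)) stop("t0 must be finite")
  compartment <- match.arg(compartment, COMPARTMENTS)
  structure(list(values = values, fs = fs, t0 = t0,
                 trace_id = as.character(trace_id),
                 neuron_id = as.character(neuron_id),
                 compartment = compartment, kind = kind),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace '%s'> %s/%s, kind=%s, %d samples @ %g Hz (%.1f s)\n",
              x$trace_id, x$neuron_id, x$compartment, x$kind,
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$values)

#' Sample times of a trace
#'
#' @param x a `trace` or `speed_trace`.
#' @return numeric vector of times in seconds, one per sample.
#' @export
trace_times <- function(x) {
  n <- if (inherits(x, "speed_trace")) length(x$speed) else length(x$values)
  x$t0 + (seq_len(n) - 1) / x$fs
}

#' Treadmill speed trace
#'
#' @param speed numeric vector of speeds in cm/s; must be non-negative.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @return An object of class `"speed_trace"`.
#' @export
speed_trace <- function(speed, fs, t0 = 0) {
  speed <- as.numeric(speed)
  if (!all(is.finite(speed))) stop("speed values must be finite")
  if (any(speed < 0)) stop("speed must be non-negative")
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive finite number")
  structure(list(speed = speed, fs = fs, t0 = t0), class = "speed_trace")
}

#' Drifting-grating stimulus schedule
#'
#' Trials are full-field drifting gratings of fixed duration separated by
#' isoluminant grey periods. Directions come from a set of equally spaced
#' angles (8 directions by default, collapsed to 4 orientations mod 180
#' degrees by the tuning stage).
#'
#' @param onsets trial onset times in seconds, strictly increasing.
#' @param directions drift direction of each trial in degrees.
#' @param stim_s grating duration in seconds (default 3).
#' @param gray_s grey-screen duration between gratings in seconds (default 4).
#' @return An object of class `"stim_schedule"`.
#' @export
stim_schedule <- function(onsets, directions, stim_s = 3, gray_s = 4) {
  onsets <- as.numeric(onsets)
  directions <- as.numeric(directions) %% 360
  if (length(onsets) != length(directions))
    stop("onsets and directions must have the same length")
  if (length(onsets) > 1 && any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing")
  if (length(onsets) > 1 && any(diff(onsets) < stim_s + gray_s - 1e-9))
    stop("inter-onset interval must be at least stim_s + gray_s")
  structure(list(onsets = onsets, directions = directions,
                 stim_s = stim_s, gray_s = gray_s),
            class = "stim_schedule")
}

#' Trial structure for baseline estimation
#'
#' Sample-index ranges (1-based, inclusive) that partition a trace into
#' trials for per-trial baseline estimation. Ranges must be ordered,
#' non-overlapping and within the trace.
#'
#' @param starts,ends integer vectors of first and last sample per trial.
#' @return data.frame with columns `start`, `end`, class `"trial_structure"`.
#' @export
trial_structure <- function(starts, ends) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) != length(ends)) stop("starts/ends length mismatch")
  if (any(ends < starts)) stop("each trial must satisfy end >= start")
  if (length(starts) > 1 && any(starts[-1] <= ends[-length(ends)]))
    stop("trials must be ordered and non-overlapping")
  structure(data.frame(start = starts, end = ends),
            class = c("trial_structure", "data.frame"))
}

check_trials_within <- function(trials, n) {
  if (any(trials$start < 1) || any(trials$end > n))
    stop("trial outside trace extent")
  invisible(trials)
}
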