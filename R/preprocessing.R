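# Raw fluorescence -> dF/F0 conversion and resampling.

#' Convert raw fluorescence to dF/F0 with a percentile baseline
#'
#' The baseline F0 is estimated per trial as the 5th percentile of the
#' low-pass-smoothed raw trace (1 Hz cutoff, zero-phase, 60th-order FIR),
#' then averaged across trials to a single scalar, so the same baseline is
#' used across all conditions of a session. The output is
#' `(F - F0) / F0`.
#'
#' @param raw a `trace` with `kind = "raw"`.
#' @param trials optional [trial_structure()]; when `NULL` the whole trace
#'   is treated as one trial (darkness-only sessions).
#' @param percentile baseline percentile (default 0.05); linear
#'   interpolation convention (`stats::quantile` type 7).
#' @param cutoff,order low-pass smoothing parameters passed to
#'   [lowpass_fir()].
#' @return a `trace` with `kind = "dff"`.
#' @export
compute_dff <- function(raw, trials = NULL, percentile = 0.05,
                        cutoff = 1, order = 60) {
  if (!inherits(raw, "trace")) stop("raw must be a trace")
  if (raw$kind != "raw") stop("compute_dff expects a trace of kind 'raw'")
  n <- length(raw$values)
  if (is.null(trials)) trials <- trial_structure(1L, n)
  check_trials_within(trials, n)
  f0_per_trial <- vapply(seq_len(nrow(trials)), function(i) {
    seg <- raw$values[trials$start[i]:trials$end[i]]
    if (length(seg) < order + 1)
      stop("trial shorter than filter order + 1 samples")
    sm <- lowpass_fir(seg, raw$fs, cutoff = cutoff, order = order)
    unname(stats::quantile(sm, percentile, type = 7))
  }, numeric(1))
  f0 <- mean(f0_per_trial)
  if (f0 <= 0) stop("baseline F0 <= 0: dF/F0 is undefined for this trace")
  out <- raw
  out$values <- (raw$values - f0) / f0
  out$kind <- "dff"
  attr(out, "f0") <- f0
  out
}

#' Convert raw fluorescence to dF/F0 with a pre-stimulus baseline (ex vivo)
#'
#' For slice recordings the baseline F0 is the mean fluorescence over a
#' stated pre-stimulus window and a background term is subtracted from the
#' denominator: `(F - F0) / (F0 - F_background)`. Baseline fluorescence in
#' distal dendrites is often very low ex vivo, so the denominator is
#' checked explicitly.
#'
#' @param raw a `trace` with `kind = "raw"`.
#' @param baseline_window numeric length-2, start and end of the baseline
#'   window in seconds (half-open).
#' @param f_background background fluorescence in the same units as the
#'   trace (default 0, in which case the formula reduces to `(F - F0)/F0`).
#' @return a `trace` with `kind = "dff"`.
#' @export
compute_dff_exvivo <- function(raw, baseline_window = c(0, 1),
                               f_background = 0) {
  if (!inherits(raw, "trace")) stop("raw must be a trace")
  if (raw$kind != "raw")
    stop("compute_dff_exvivo expects a trace of kind 'raw'")
  tt <- trace_times(raw)
  idx <- which(tt >= baseline_window[1] & tt < baseline_window[2])
  if (length(idx) == 0) stop("baseline window contains no samples")
  f0 <- mean(raw$values[idx])
  denom <- f0 - f_background
  if (denom <= 0)
    stop(sprintf(
      "F0 (%.4g) must exceed F_background (%.4g): denominator of dF/F0 is not positive",
      f0, f_background))
  out <- raw
  out$values <- (raw$values - f0) / denom
  out$kind <- "dff"
  attr(out, "f0") <- f0
  out
}

#' Downsample a trace by bin averaging
#'
#' Samples are grouped into non-overlapping time bins of width
#' `1/target_fs` and averaged (anti-aliasing by integration rather than
#' decimation). Upsampling is refused.
#'
#' @param trace a `trace`.
#' @param target_fs target sampling rate in Hz, at most `trace$fs`.
#' @return a `trace` at `target_fs`.
#' @export
resample_trace <- function(trace, target_fs) {
  if (!inherits(trace, "trace")) stop("trace must be a trace object")
  if (target_fs > trace$fs + 1e-12)
    stop("target_fs exceeds the trace sampling rate; upsampling not supported")
  if (abs(target_fs - trace$fs) < 1e-12) return(trace)
  tt <- trace_times(trace) - trace$t0
  bin <- floor(tt * target_fs + 1e-9)
  v <- as.numeric(tapply(trace$values, bin, mean))
  out <- trace
  out$values <- v
  out$fs <- target_fs
  out
}
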