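# Zero-phase filtering helpers. All filters are applied forward-backward so
# the net phase response is zero; edges are handled by odd (point-mirrored)
# reflection padding so that constant and slowly varying signals pass through
# without boundary transients.

# Odd-reflection pad of length `pad` on both ends.
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(list(x = x, pad = 0L))
  left  <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  list(x = c(left, x, right), pad = pad)
}

# Forward-backward application of an ARMA filter (b, a) with reflection
# padding of at least one filter length.
zero_phase <- function(b, a, x) {
  b <- as.numeric(b); a <- as.numeric(a)
  nf <- max(length(b), length(a))
  p <- reflect_pad(x, 3L * (nf - 1L))
  y <- as.numeric(signal::filter(b, a, p$x))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  if (p$pad > 0L) y <- y[seq(p$pad + 1L, p$pad + length(x))]
  y
}

#' Zero-phase FIR low-pass filter
#'
#' Windowed-sinc (Hamming) FIR low-pass, applied forward-backward with
#' reflection padding. Used to smooth raw fluorescence before taking the
#' baseline percentile (order 60, 1 Hz cutoff by default).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz.
#' @param order FIR order (number of taps minus one).
#' @return filtered numeric vector, same length as `x`.
#' @export
lowpass_fir <- function(x, fs, cutoff = 1, order = 60) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (length(x) < order + 1) stop("input shorter than filter order + 1")
  b <- as.numeric(signal::fir1(order, cutoff / (fs / 2), type = "low"))
  b <- b / sum(b)  # exact unit DC gain so the baseline is not biased
  zero_phase(b, 1, x)
}

#' Zero-phase Butterworth high-pass filter
#'
#' Used by the noise estimator (order 9, 0.6 Hz cutoff by default): the
#' high-passed dF/F0 trace retains the noise floor while indicator
#' transients, which live below ~0.6 Hz, are removed.
#'
#' @inheritParams lowpass_fir
#' @param order filter order.
#' @return filtered numeric vector, same length as `x`.
#' @export
highpass_butter <- function(x, fs, cutoff = 0.6, order = 9) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bt <- signal::butter(order, cutoff / (fs / 2), type = "high")
  zero_phase(bt$b, bt$a, x)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Used by the locomotion classifier (order 2, 0.25 Hz cutoff by default).
#'
#' @inheritParams highpass_butter
#' @return filtered numeric vector, same length as `x`.
#' @export
lowpass_butter <- function(x, fs, cutoff = 0.25, order = 2) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  zero_phase(bt$b, bt$a, x)
}

# Centred moving average over a window of `w` samples, truncated at the
# boundaries (each output is the mean of the available samples).
centered_mean <- function(x, w) {
  n <- length(x)
  half <- floor(w / 2)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
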