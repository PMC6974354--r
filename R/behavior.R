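# Behavioural-state segmentation from the treadmill speed trace.

#' Classify samples into stationary / locomotion / excluded states
#'
#' Locomotion requires all three criteria at a sample: instantaneous
#' speed at or above `speed_thresh`, 0.25 Hz low-pass filtered speed at or
#' above it, and mean speed over a centred 2 s window at or above it. Gaps
#' between
#' locomotion periods shorter than `merge_gap_s` are merged into
#' locomotion. Stationary requires instantaneous speed < `speed_thresh`;
#' stationary samples less than `still_after_s` after a locomotion offset
#' or less than `still_before_s` before an onset are excluded from
#' analysis, as are samples meeting neither definition.
#'
#' The speed trace is expected to have been interpolated/resampled to the
#' imaging analysis rate beforehand.
#'
#' @param speed a [speed_trace()].
#' @param speed_thresh speed threshold in cm/s (default 0.1).
#' @param lp_cutoff low-pass cutoff in Hz (default 0.25; 2nd-order
#'   zero-phase Butterworth).
#' @param mean_window_s centred-mean window in seconds (default 2),
#'   truncated at the trace boundaries.
#' @param merge_gap_s maximum inter-locomotion gap merged into locomotion,
#'   seconds (default 0.5).
#' @param still_after_s stationary exclusion zone after a locomotion
#'   offset, seconds (default 3).
#' @param still_before_s stationary exclusion zone before a locomotion
#'   onset, seconds (default 0.2).
#' @return object of class `"behavior_labels"`: factor `state` per sample
#'   with levels stationary/locomotion/transition/excluded (transition only
#'   after [transition_windows()]), `fs`, `t0`, and `bouts` (data.frame of
#'   locomotion onset/offset times; offsets are half-open).
#' @export
classify_behavior <- function(speed, speed_thresh = 0.1, lp_cutoff = 0.25,
                              mean_window_s = 2, merge_gap_s = 0.5,
                              still_after_s = 3, still_before_s = 0.2) {
  if (!inherits(speed, "speed_trace")) stop("speed must be a speed_trace")
  v <- speed$speed
  fs <- speed$fs
  if (length(v) < 2 * fs) stop("speed trace shorter than 2 s")
  inst <- v >= speed_thresh
  lp <- lowpass_butter(v, fs, cutoff = lp_cutoff, order = 2) >= speed_thresh
  cm <- centered_mean(v, round(mean_window_s * fs)) >= speed_thresh
  loco <- inst & lp & cm

  # merge gaps shorter than merge_gap_s between locomotion periods
  r <- rle(loco)
  if (length(r$lengths) > 2) {
    for (k in 2:(length(r$values) - 1))
      if (!r$values[k] && r$values[k - 1] && r$values[k + 1] &&
          r$lengths[k] / fs < merge_gap_s)
        r$values[k] <- TRUE
    loco <- inverse.rle(r)
    r <- rle(loco)
  }

  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bi <- which(r$values)
  tt <- speed$t0 + (seq_along(v) - 1) / fs
  bouts <- data.frame(onset = tt[starts[bi]],
                      offset = speed$t0 + ends[bi] / fs)

  state <- rep("excluded", length(v))
  state[loco] <- "locomotion"
  state[!loco & v < speed_thresh] <- "stationary"
  if (nrow(bouts) > 0) {
    for (k in seq_len(nrow(bouts))) {
      drop <- (tt >= bouts$offset[k] & tt < bouts$offset[k] + still_after_s) |
              (tt >= bouts$onset[k] - still_before_s & tt < bouts$onset[k])
      state[drop & state == "stationary"] <- "excluded"
    }
  }
  structure(list(state = factor(state, levels = c("stationary", "locomotion",
                                                  "transition", "excluded")),
                 fs = fs, t0 = speed$t0, bouts = bouts),
            class = "behavior_labels")
}

#' @export
print.behavior_labels <- function(x, ...) {
  tb <- table(x$state)
  cat(sprintf("<behavior_labels> %d samples @ %g Hz; %d bouts; %s\n",
              length(x$state), x$fs, nrow(x$bouts),
              paste(names(tb), tb, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Mark behavioural-transition windows
#'
#' Transitions span from `pre_onset_s` before to `post_onset_s` after each
#' locomotion onset, and from `pre_offset_s` before to `post_offset_s`
#' after each offset; the post-offset window is truncated when another
#' locomotion period begins before it ends. Transition samples are removed
#' from both the stationary and locomotion masks.
#'
#' @param labels a [classify_behavior()] result.
#' @param pre_onset_s,post_onset_s window around locomotion onsets, seconds
#'   (defaults 2 and 1).
#' @param pre_offset_s,post_offset_s window around locomotion offsets,
#'   seconds (defaults 1 and 20).
#' @return `behavior_labels` with transition samples relabelled.
#' @export
transition_windows <- function(labels, pre_onset_s = 2, post_onset_s = 1,
                               pre_offset_s = 1, post_offset_s = 20) {
  if (!inherits(labels, "behavior_labels"))
    stop("labels must be behavior_labels")
  b <- labels$bouts
  if (nrow(b) == 0) return(labels)
  tt <- labels$t0 + (seq_along(labels$state) - 1) / labels$fs
  st <- as.character(labels$state)
  for (k in seq_len(nrow(b))) {
    st[tt >= b$onset[k] - pre_onset_s &
       tt < b$onset[k] + post_onset_s] <- "transition"
    post_end <- b$offset[k] + post_offset_s
    if (k < nrow(b)) post_end <- min(post_end, b$onset[k + 1])
    st[tt >= b$offset[k] - pre_offset_s & tt < post_end] <- "transition"
  }
  labels$state <- factor(st, levels = levels(labels$state))
  labels
}

#' Per-sample behavioural state at event or trial times
#'
#' @param labels a `behavior_labels`.
#' @param times query times in seconds.
#' @return character vector of states at the nearest sample.
#' @export
state_at <- function(labels, times) {
  idx <- pmin(pmax(round((times - labels$t0) * labels$fs) + 1L, 1L),
              length(labels$state))
  as.character(labels$state[idx])
}
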