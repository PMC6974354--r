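# Orientation tuning: trial-averaged responses, selectivity index, and the
# complex resultant vector.

#' Trial-averaged responses per orientation
#'
#' Averages dF/F0 over each grating presentation window, optionally keeping
#' only trials spent in a given behavioural state, then averages across
#' trials of the same orientation. Opposite drift directions are collapsed
#' to orientations mod 180 degrees.
#'
#' @param dff a dF/F0 `trace`.
#' @param schedule a [stim_schedule()].
#' @param labels optional [classify_behavior()] result for state filtering.
#' @param state optional state name (`"stationary"`, `"locomotion"`, ...);
#'   a trial qualifies when more than `min_state_fraction` of its samples
#'   are in that state.
#' @param min_state_fraction fraction of within-trial samples required in
#'   `state` (default 0.5).
#' @return data.frame of class `"tuning_curve"` with columns `orientation`
#'   (degrees), `mean_response`, `n_trials`. Orientations with no
#'   qualifying trial have `NA` response.
#' @export
trial_average <- function(dff, schedule, labels = NULL, state = NULL,
                          min_state_fraction = 0.5) {
  if (!inherits(dff, "trace") || dff$kind != "dff")
    stop("dff must be a trace of kind 'dff'")
  tt <- trace_times(dff)
  if (any(schedule$onsets + schedule$stim_s > max(tt) + 1 / dff$fs))
    stop("trials extend beyond the trace")
  ori <- schedule$directions %% 180
  resp <- rep(NA_real_, length(schedule$onsets))
  keep <- rep(TRUE, length(schedule$onsets))
  for (i in seq_along(schedule$onsets)) {
    idx <- which(tt >= schedule$onsets[i] &
                 tt < schedule$onsets[i] + schedule$stim_s)
    if (length(idx) == 0) { keep[i] <- FALSE; next }
    if (!is.null(state)) {
      frac <- mean(state_at(labels, tt[idx]) == state)
      if (frac <= min_state_fraction) { keep[i] <- FALSE; next }
    }
    resp[i] <- mean(dff$values[idx])
  }
  u <- sort(unique(ori))
  mean_response <- vapply(u, function(o) {
    sel <- keep & ori == o
    if (!any(sel)) NA_real_ else mean(resp[sel])
  }, numeric(1))
  n_trials <- vapply(u, function(o) sum(keep & ori == o), integer(1))
  structure(data.frame(orientation = u, mean_response = mean_response,
                       n_trials = n_trials),
            class = c("tuning_curve", "data.frame"))
}

as_response_vector <- function(responses) {
  if (inherits(responses, "tuning_curve")) {
    r <- responses$mean_response
    names(r) <- responses$orientation
    return(r)
  }
  if (is.null(names(responses)))
    stop("responses must be named by orientation (degrees)")
  responses
}

#' Orientation selectivity index
#'
#' `OSI = (O_pref - O_orth) / (O_pref + O_orth)`, where O_pref is the mean
#' response at the preferred orientation (the orientation with the maximal
#' trial-averaged response) and O_orth the response at the orientation
#' orthogonal to it (preferred + 90 degrees, mod 180).
#'
#' @param responses a `tuning_curve` or numeric vector named by orientation
#'   in degrees.
#' @return list with `osi`, `preferred` (degrees), `o_pref`, `o_orth`.
#' @export
osi <- function(responses) {
  r <- as_response_vector(responses)
  r <- r[!is.na(r)]
  if (length(r) == 0) stop("no responses")
  ori <- as.numeric(names(r)) %% 180
  pref <- ori[which.max(r)]
  orth <- (pref + 90) %% 180
  j <- which(abs(ori - orth) < 1e-6)
  if (length(j) == 0) stop("response at the orthogonal orientation missing")
  o_pref <- max(r); o_orth <- r[[j[1]]]
  if (o_pref + o_orth <= 0)
    stop("O_pref + O_orth <= 0: OSI undefined")
  list(osi = (o_pref - o_orth) / (o_pref + o_orth), preferred = pref,
       o_pref = o_pref, o_orth = o_orth)
}

#' Complex resultant vector of a tuning curve
#'
#' `V = sum_k R_k exp(2 i theta_k) / sum_k R_k` over orientations theta_k
#' (in radians), with negative mean responses floored at zero. The
#' preferred orientation is `arg(V) / 2` mod 180 degrees and `|V|` is a
#' tuning-strength index in `[0, 1]`.
#'
#' @param responses a `tuning_curve` or numeric vector named by orientation
#'   in degrees.
#' @return list with `V` (complex), `magnitude`, `preferred` (degrees;
#'   `NA` when `|V|` is numerically zero, e.g. perfectly uniform
#'   responses).
#' @export
resultant_vector <- function(responses) {
  r <- as_response_vector(responses)
  r <- r[!is.na(r)]
  if (length(r) == 0) stop("no responses")
  r <- pmax(r, 0)
  if (sum(r) <= 0)
    stop("all responses are zero: resultant vector undefined")
  th <- as.numeric(names(r)) * pi / 180
  V <- sum(r * exp(2i * th)) / sum(r)
  mag <- Mod(V)
  preferred <- if (mag < 1e-12) NA_real_ else (Arg(V) / 2 * 180 / pi) %% 180
  list(V = V, magnitude = mag, preferred = preferred)
}
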