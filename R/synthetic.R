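# Forward simulator: sparse somatic transients with burst frequencies,
# distance- and amplitude-dependent somatofugal propagation, rare
# tuft-initiated global events, indicator kinetics, and additive Gaussian
# noise. The hidden ground truth (event times, amplitudes, propagation
# flags) is returned alongside the traces for parameter-recovery tests.

#' Normalised calcium indicator impulse response
#'
#' Difference-of-exponentials kernel
#' \eqn{k(t) = (e^{-t/\tau_d} - e^{-t/\tau_r}) / k_{max}} for \eqn{t \ge 0},
#' scaled so its peak equals 1. An event of amplitude `a` therefore
#' contributes a transient whose peak dF/F0 equals `a`.
#'
#' @param t times in seconds (may be negative; the kernel is causal).
#' @param rise rise time constant in seconds.
#' @param decay decay time constant in seconds; must exceed `rise`.
#' @return kernel values at `t`.
#' @export
calcium_kernel <- function(t, rise = 0.18, decay = 1.0) {
  if (!(rise > 0 && decay > rise)) stop("need 0 < rise < decay")
  raw <- ifelse(t >= 0, exp(-t / decay) - exp(-t / rise), 0)
  raw / kernel_peak(rise, decay)
}

#' Peak time and value of the unscaled difference-of-exponentials kernel
#'
#' Closed forms: the peak is at
#' \eqn{t^* = \frac{\tau_r \tau_d}{\tau_d - \tau_r}\log(\tau_d/\tau_r)}.
#'
#' @inheritParams calcium_kernel
#' @return `kernel_peak_time`: the peak time in seconds; `kernel_peak`: the
#'   unscaled kernel value at the peak.
#' @export
kernel_peak_time <- function(rise = 0.18, decay = 1.0) {
  if (!(rise > 0 && decay > rise)) stop("need 0 < rise < decay")
  rise * decay / (decay - rise) * log(decay / rise)
}

#' @rdname kernel_peak_time
#' @export
kernel_peak <- function(rise = 0.18, decay = 1.0) {
  ts <- kernel_peak_time(rise, decay)
  exp(-ts / decay) - exp(-ts / rise)
}

#' Logistic amplitude-dependent propagation model
#'
#' Survival probability of a somatically initiated transient across one
#' dendritic segment: logistic in the event amplitude (small events
#' attenuate more), fully gated on above a critical within-burst spike
#' frequency (back-propagating spike trains above the critical frequency
#' recruit distal calcium electrogenesis and always propagate).
#'
#' @param midpoint amplitude (dF/F0) at which survival is 0.5 for
#'   sub-critical bursts; one value per segment or a single value.
#' @param slope logistic scale in amplitude units.
#' @param critical_freq burst frequency in Hz at and above which survival
#'   is 1 (default 50).
#' @return a function `(amplitude, freq, segment)` returning survival
#'   probabilities in `[0, 1]`.
#' @export
attenuation_logistic <- function(midpoint, slope = 0.08, critical_freq = 50) {
  force(midpoint); force(slope); force(critical_freq)
  function(amplitude, freq, segment) {
    m <- if (length(midpoint) > 1) midpoint[[segment]] else midpoint
    p <- stats::plogis((amplitude - m) / slope)
    p[rep_len(freq >= critical_freq, length(p))] <- 1
    p
  }
}

#' Constant-survival propagation model
#'
#' @param p survival probability per segment (single value or one per
#'   segment), in `[0, 1]`.
#' @return a function usable as `attenuation` in [synth_config()].
#' @export
attenuation_constant <- function(p) {
  if (any(p < 0 | p > 1)) stop("survival probabilities must lie in [0, 1]")
  force(p)
  function(amplitude, freq, segment) {
    pr <- if (length(p) > 1) p[[segment]] else p
    rep(pr, length(amplitude))
  }
}

#' Simulation configuration
#'
#' Parameters of the forward model. Defaults emulate dual-plane imaging of a
#' GCaMP6s-labelled layer 5 neuron: sparse somatic transients (merged
#' bursts), a categorical distribution of within-burst spike frequencies,
#' log-normal event amplitudes, logistic per-segment somatofugal survival
#' gated by a 50 Hz critical frequency, rare tuft-initiated global events,
#' and slow-indicator kinetics.
#'
#' @param n_neurons number of neurons to simulate.
#' @param duration recording length in seconds.
#' @param fs sampling rate in Hz (4.8 emulates per-plane dual-plane
#'   imaging; 120 emulates single-plane imaging).
#' @param soma_event_rate somatic transient rate in events/min.
#' @param burst_freq_probs named probability vector over within-burst spike
#'   frequencies in Hz; names are the frequencies.
#' @param amplitude_meanlog,amplitude_sdlog log-normal parameters of the
#'   true somatic event amplitude (dF/F0).
#' @param attenuation function `(amplitude, freq, segment)` giving the
#'   probability that an event survives one somatofugal segment; see
#'   [attenuation_logistic()].
#' @param segment_gain multiplicative amplitude gain per crossed segment
#'   (distal amplitude = proximal amplitude x gain).
#' @param tuft_initiated_rate rate of tuft-initiated global events in
#'   events/min.
#' @param tuft_soma_survival probability that a tuft-initiated event is
#'   also seen in the compartments below the tuft.
#' @param kernel_rise,kernel_decay indicator kinetics in seconds
#'   (defaults emulate a slow GCaMP6s-like indicator; use 0.05/0.3 for a
#'   fast 6f-like one).
#' @param noise_sd i.i.d. Gaussian noise SD in dF/F0 units.
#' @param baseline_f0 baseline fluorescence in arbitrary units.
#' @param compartments ordered somatofugal chain of compartment names.
#' @param seed integer seed; `generate_neuron()` derives a per-neuron
#'   stream from it.
#' @return object of class `"synth_config"`.
#' @export
synth_config <- function(n_neurons = 1,
                         duration = 600,
                         fs = 4.8,
                         soma_event_rate = 4,
                         burst_freq_probs = c("10" = 0.35, "25" = 0.30,
                                              "50" = 0.20, "100" = 0.15),
                         amplitude_meanlog = log(0.35),
                         amplitude_sdlog = 0.6,
                         attenuation = attenuation_logistic(
                           midpoint = c(pTrunk = 0.10, dTrunk = 0.06,
                                        tuft = 0.16)),
                         segment_gain = 1,
                         tuft_initiated_rate = 0.05,
                         tuft_soma_survival = 0.986,
                         kernel_rise = 0.18,
                         kernel_decay = 1.0,
                         noise_sd = 0.015,
                         baseline_f0 = 100,
                         compartments = c("soma", "pTrunk", "dTrunk", "tuft"),
                         seed = 1L) {
  num_fields <- list(n_neurons = n_neurons, duration = duration, fs = fs,
                     soma_event_rate = soma_event_rate,
                     amplitude_meanlog = amplitude_meanlog,
                     amplitude_sdlog = amplitude_sdlog,
                     tuft_initiated_rate = tuft_initiated_rate,
                     tuft_soma_survival = tuft_soma_survival,
                     kernel_rise = kernel_rise, kernel_decay = kernel_decay,
                     noise_sd = noise_sd, baseline_f0 = baseline_f0,
                     seed = seed)
  for (nm in names(num_fields))
    if (!all(is.finite(num_fields[[nm]])))
      stop(sprintf("config field '%s' must be finite", nm))
  if (duration <= 0) stop("config field 'duration' must be positive")
  if (fs <= 0) stop("config field 'fs' must be positive")
  if (soma_event_rate < 0) stop("config field 'soma_event_rate' must be >= 0")
  if (tuft_initiated_rate < 0)
    stop("config field 'tuft_initiated_rate' must be >= 0")
  if (tuft_soma_survival < 0 || tuft_soma_survival > 1)
    stop("config field 'tuft_soma_survival' must lie in [0, 1]")
  if (!(kernel_rise > 0 && kernel_rise < kernel_decay))
    stop("config fields must satisfy 0 < kernel_rise < kernel_decay")
  if (noise_sd < 0) stop("config field 'noise_sd' must be >= 0")
  if (baseline_f0 <= 0) stop("config field 'baseline_f0' must be positive")
  if (abs(sum(burst_freq_probs) - 1) > 1e-8 || any(burst_freq_probs < 0))
    stop("config field 'burst_freq_probs' must be a probability vector")
  if (!is.function(attenuation)) stop("'attenuation' must be a function")
  if (length(compartments) < 2) stop("need at least two compartments")
  structure(list(n_neurons = n_neurons, duration = duration, fs = fs,
                 soma_event_rate = soma_event_rate,
                 burst_freq_probs = burst_freq_probs,
                 amplitude_meanlog = amplitude_meanlog,
                 amplitude_sdlog = amplitude_sdlog,
                 attenuation = attenuation, segment_gain = segment_gain,
                 tuft_initiated_rate = tuft_initiated_rate,
                 tuft_soma_survival = tuft_soma_survival,
                 kernel_rise = kernel_rise, kernel_decay = kernel_decay,
                 noise_sd = noise_sd, baseline_f0 = baseline_f0,
                 compartments = compartments, seed = as.integer(seed)),
            class = "synth_config")
}

segment_names <- function(config) config$compartments[-1]

#' Expected per-segment survival under a configuration
#'
#' Marginal survival probability of a somatic event across one segment,
#' integrating the attenuation model over the configured amplitude and
#' burst-frequency distributions. Used by recovery tests as the configured
#' truth against which empirical distal/proximal frequency ratios are
#' compared.
#'
#' @param config a [synth_config()].
#' @param segment segment name (a non-soma compartment).
#' @return expected survival probability in `[0, 1]`.
#' @export
mean_survival <- function(config, segment) {
  freqs <- as.numeric(names(config$burst_freq_probs))
  probs <- config$burst_freq_probs
  total <- 0
  for (i in seq_along(freqs)) {
    f <- function(a)
      config$attenuation(a, freqs[i], segment) *
        stats::dlnorm(a, config$amplitude_meanlog, config$amplitude_sdlog)
    total <- total + probs[i] *
      stats::integrate(f, 0, Inf, rel.tol = 1e-8)$value
  }
  unname(total)
}

# Render events into a fluorescence trace:
# F(t) = F0 * (1 + sum_i a_i k(t - t_i)) + N(0, noise_sd * F0).
render_trace <- function(times, amps, config, compartment, neuron_id,
                         trace_id) {
  n <- round(config$duration * config$fs)
  tt <- (seq_len(n) - 1) / config$fs
  dff <- numeric(n)
  span <- 8 * config$kernel_decay
  for (i in seq_along(times)) {
    i0 <- max(1L, floor(times[i] * config$fs) + 1L)
    i1 <- min(n, ceiling((times[i] + span) * config$fs) + 1L)
    if (i0 > n) next
    idx <- i0:i1
    dff[idx] <- dff[idx] + amps[i] *
      calcium_kernel(tt[idx] - times[i], config$kernel_rise,
                     config$kernel_decay)
  }
  values <- config$baseline_f0 * (1 + dff)
  if (config$noise_sd > 0)
    values <- values + stats::rnorm(n, 0, config$noise_sd * config$baseline_f0)
  new_trace(values, fs = config$fs, trace_id = trace_id,
            neuron_id = neuron_id, compartment = compartment, kind = "raw")
}

#' Simulate one neuron's compartment traces with hidden ground truth
#'
#' Draws somatic transients as a Poisson process (each transient stands for
#' one burst; within-burst spikes are not resolved by the indicator), assigns
#' each a burst frequency and log-normal amplitude, propagates it
#' somatofugally segment by segment with survival given by the configured
#' attenuation model, adds rare tuft-initiated global events, and renders
#' each compartment's fluorescence as baseline plus amplitude-scaled kernel
#' plus i.i.d. Gaussian noise.
#'
#' @param config a [synth_config()].
#' @param neuron_id integer neuron index (used to derive the RNG stream).
#' @return list with `traces` (named list of raw [new_trace()] objects, one
#'   per compartment) and `truth` (class `"synth_truth"`): event table
#'   (`time`, `amplitude`, `burst_freq`, `origin`), logical presence matrix
#'   events x compartments, per-compartment amplitude matrix, and the seed.
#' @export
generate_neuron <- function(config, neuron_id = 1L) {
  if (!inherits(config, "synth_config")) stop("config must be a synth_config")
  set.seed(config$seed + 104729L * (as.integer(neuron_id) - 1L))
  comps <- config$compartments
  segs <- segment_names(config)

  n_soma <- stats::rpois(1, config$soma_event_rate / 60 * config$duration)
  t_soma <- sort(stats::runif(n_soma, 0, config$duration))
  freqs <- as.numeric(names(config$burst_freq_probs))
  f_soma <- if (n_soma > 0)
    sample(freqs, n_soma, replace = TRUE, prob = config$burst_freq_probs)
  else numeric(0)
  a_soma <- stats::rlnorm(n_soma, config$amplitude_meanlog,
                          config$amplitude_sdlog)

  n_tuft <- stats::rpois(1, config$tuft_initiated_rate / 60 * config$duration)
  t_tuft <- sort(stats::runif(n_tuft, 0, config$duration))
  a_tuft <- stats::rlnorm(n_tuft, config$amplitude_meanlog,
                          config$amplitude_sdlog)

  n_ev <- n_soma + n_tuft
  events <- data.frame(
    time = c(t_soma, t_tuft),
    amplitude = c(a_soma, a_tuft),
    burst_freq = c(f_soma, rep(NA_real_, n_tuft)),
    origin = rep(c("soma", "tuft"), c(n_soma, n_tuft)))
  ord <- order(events$time)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL

  presence <- matrix(FALSE, n_ev, length(comps),
                     dimnames = list(NULL, comps))
  gains <- rep_len(config$segment_gain, length(segs))
  amp <- matrix(0, n_ev, length(comps), dimnames = list(NULL, comps))
  for (i in seq_len(n_ev)) {
    if (events$origin[i] == "soma") {
      presence[i, "soma"] <- TRUE
      amp[i, "soma"] <- events$amplitude[i]
      a <- events$amplitude[i]
      for (k in seq_along(segs)) {
        p <- config$attenuation(events$amplitude[i], events$burst_freq[i],
                                segs[k])
        if (stats::runif(1) >= p) break
        a <- a * gains[k]
        presence[i, segs[k]] <- TRUE
        amp[i, segs[k]] <- a
      }
    } else {
      # tuft-initiated: always present in the most distal compartment;
      # reaches all proximal compartments together with probability
      # tuft_soma_survival (a regenerative global event).
      distal <- comps[length(comps)]
      presence[i, distal] <- TRUE
      amp[i, distal] <- events$amplitude[i]
      if (stats::runif(1) < config$tuft_soma_survival) {
        presence[i, ] <- TRUE
        amp[i, ] <- events$amplitude[i]
      }
    }
  }

  traces <- vector("list", length(comps))
  names(traces) <- comps
  for (ci in seq_along(comps)) {
    keep <- presence[, ci]
    traces[[ci]] <- render_trace(events$time[keep], amp[keep, ci], config,
                                 compartment = comps[ci],
                                 neuron_id = as.character(neuron_id),
                                 trace_id = sprintf("n%s_%s", neuron_id,
                                                    comps[ci]))
  }

  truth <- structure(list(events = events, presence = presence,
                          amplitudes = amp, neuron_id = neuron_id,
                          seed = config$seed, compartments = comps),
                     class = "synth_truth")
  list(traces = traces, truth = truth)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("<synth_truth> neuron %s: %d events (%d somatic, %d tuft-initiated)\n",
              x$neuron_id, nrow(x$events), sum(x$events$origin == "soma"),
              sum(x$events$origin == "tuft")))
  invisible(x)
}

#' Ground-truth event series for one compartment
#'
#' Converts the simulator's hidden truth into the `event_series` shape the
#' coupling stage consumes, bypassing detection. Event times are the true
#' underlying times; amplitudes are the true per-compartment amplitudes,
#' normalised to the compartment maximum.
#'
#' @param truth a `synth_truth` from [generate_neuron()].
#' @param compartment compartment name.
#' @return an `event_series`.
#' @export
truth_events <- function(truth, compartment) {
  if (!inherits(truth, "synth_truth")) stop("truth must be a synth_truth")
  keep <- truth$presence[, compartment]
  amp <- truth$amplitudes[keep, compartment]
  norm_max <- if (length(amp)) max(amp) else NA_real_
  events <- data.frame(peak_time = truth$events$time[keep],
                       peak_index = NA_integer_,
                       value = amp, amplitude = amp,
                       norm_amplitude = if (length(amp)) amp / norm_max
                                        else numeric(0))
  structure(list(events = events,
                 trace_id = sprintf("truth_n%s_%s", truth$neuron_id,
                                    compartment),
                 neuron_id = as.character(truth$neuron_id),
                 compartment = compartment, fs = NA_real_,
                 noise_sd = NA_real_, multiplier = NA_real_,
                 norm_max = norm_max),
            class = "event_series")
}

#' Generate a treadmill speed trace from a bout specification
#'
#' @param duration total duration in seconds.
#' @param fs sampling rate in Hz.
#' @param bouts data.frame with columns `start`, `stop` (seconds) and
#'   `speed` (cm/s); bouts must lie in `[0, duration]` and not overlap.
#'   Bout intervals are half-open `[start, stop)`.
#' @param jitter_sd Gaussian jitter SD added within bouts (cm/s); the
#'   result is clipped at 0.
#' @param seed optional integer seed for the jitter.
#' @return a [speed_trace()].
#' @export
generate_speed <- function(duration, fs, bouts = NULL, jitter_sd = 0,
                           seed = NULL) {
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  v <- numeric(n)
  if (!is.null(bouts) && nrow(bouts) > 0) {
    b <- bouts[order(bouts$start), , drop = FALSE]
    if (any(b$start < 0) || any(b$stop > duration + 1e-9))
      stop("bouts must lie within [0, duration]")
    if (nrow(b) > 1 && any(b$start[-1] < b$stop[-nrow(b)]))
      stop("bouts must not overlap")
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(nrow(b))) {
      idx <- which(tt >= b$start[i] & tt < b$stop[i])
      v[idx] <- b$speed[i]
      if (jitter_sd > 0)
        v[idx] <- pmax(0, v[idx] + stats::rnorm(length(idx), 0, jitter_sd))
    }
  }
  speed_trace(v, fs)
}

#' Per-trial response gains with a target orientation selectivity
#'
#' Builds multiplicative trial gains so that the noiseless trial-averaged
#' tuning curve has a given preferred orientation and orientation
#' selectivity index, OSI = (O_pref - O_orth) / (O_pref + O_orth). The gain
#' at the orthogonal orientation is obtained by inverting the OSI formula,
#' `g_orth = gain * (1 - osi) / (1 + osi)`; intermediate orientations follow
#' a raised-cosine profile between the two.
#'
#' @param schedule a [stim_schedule()].
#' @param preferred preferred orientation in degrees (mod 180).
#' @param osi_target target OSI in `[0, 1]`.
#' @param gain response gain at the preferred orientation.
#' @return numeric vector of per-trial gains, with the noiseless tuning
#'   curve (per orientation) as attribute `"curve"`.
#' @export
generate_tuned_responses <- function(schedule, preferred, osi_target,
                                     gain = 1) {
  if (osi_target < 0 || osi_target > 1) stop("osi_target must lie in [0, 1]")
  ori <- schedule$directions %% 180
  preferred <- preferred %% 180
  d <- abs(ori - preferred)
  d <- pmin(d, 180 - d)
  g_orth <- gain * (1 - osi_target) / (1 + osi_target)
  g <- g_orth + (gain - g_orth) * (1 + cos(2 * d * pi / 180)) / 2
  u <- sort(unique(ori))
  du <- pmin(abs(u - preferred), 180 - abs(u - preferred))
  curve <- g_orth + (gain - g_orth) * (1 + cos(2 * du * pi / 180)) / 2
  names(curve) <- u
  attr(g, "curve") <- curve
  g
}
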