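# Ex vivo stimulation-trial analysis: sham-calibrated detection of evoked
# calcium transients in soma and distal dendrite (nexus).

#' Ex vivo stimulation trial
#'
#' One slice-imaging trial: semi-simultaneous soma and dendrite traces,
#' stimulation metadata, and the time at which stimulation ceased. Trials
#' are 6 s with a 1 s pre-stimulus baseline by default; sham trials carry a
#' nominal offset so their peaks are measured in a matched window.
#'
#' @param soma,dendrite raw `trace` objects.
#' @param stim_type `"somatic"`, `"dendritic"` or `"sham"`.
#' @param freq pulse frequency in Hz (NA for sham).
#' @param n_pulses pulses per train (default 10).
#' @param stim_offset time of stimulation cessation, seconds.
#' @param n_ap number of action potentials evoked (metadata only).
#' @return object of class `"exvivo_trial"`.
#' @export
exvivo_trial <- function(soma, dendrite, stim_type, freq = NA_real_,
                         n_pulses = 10, stim_offset = 1.5, n_ap = NA_integer_) {
  stim_type <- match.arg(stim_type, c("somatic", "dendritic", "sham"))
  structure(list(soma = soma, dendrite = dendrite, stim_type = stim_type,
                 freq = freq, n_pulses = n_pulses,
                 stim_offset = stim_offset, n_ap = n_ap),
            class = "exvivo_trial")
}

#' Simulate a set of ex vivo stimulation trials
#'
#' Somatic response amplitude grows monotonically and saturates with pulse
#' frequency; the dendritic (nexus) response to somatic stimulation is zero
#' below the critical back-propagation frequency and follows the somatic
#' curve above it. Dendritic stimulation drives both compartments at all
#' frequencies. Sham trials contain baseline and noise only.
#'
#' @param freqs pulse frequencies in Hz.
#' @param n_per_freq stimulation trials per frequency.
#' @param n_sham number of sham trials.
#' @param stim_type `"somatic"` or `"dendritic"`.
#' @param soma_max saturating somatic response amplitude (dF/F0).
#' @param f_half frequency at half-maximal somatic response (Hz).
#' @param critical_freq frequency at and above which somatically driven
#'   spiking recruits the dendrite (default 50 Hz).
#' @param dend_gain dendritic amplitude as a fraction of the somatic one.
#' @param noise_sd Gaussian noise SD in dF/F0 units.
#' @param duration,baseline_s,fs trial length, pre-stimulus baseline and
#'   sampling rate (defaults 6 s, 1 s, 20 Hz).
#' @param n_pulses pulses per train.
#' @param kernel_rise,kernel_decay indicator kinetics, seconds.
#' @param baseline_f0 baseline fluorescence, arbitrary units.
#' @param seed integer seed.
#' @return list of [exvivo_trial()] objects.
#' @export
simulate_exvivo <- function(freqs = c(5, 10, 25, 50, 100, 200),
                            n_per_freq = 5, n_sham = 10,
                            stim_type = c("somatic", "dendritic"),
                            soma_max = 1.5, f_half = 25,
                            critical_freq = 50, dend_gain = 0.8,
                            noise_sd = 0.03, duration = 6, baseline_s = 1,
                            fs = 20, n_pulses = 10, kernel_rise = 0.18,
                            kernel_decay = 1.0, baseline_f0 = 50,
                            seed = 1L) {
  stim_type <- match.arg(stim_type)
  set.seed(seed)
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  make_trace <- function(amp, t_event, compartment, id) {
    dff <- if (amp > 0)
      amp * calcium_kernel(tt - t_event, kernel_rise, kernel_decay)
    else numeric(n)
    v <- baseline_f0 * (1 + dff) +
      stats::rnorm(n, 0, noise_sd * baseline_f0)
    new_trace(v, fs = fs, trace_id = id, compartment = compartment,
              kind = "raw")
  }
  trials <- list()
  for (f in freqs) {
    stim_end <- baseline_s + (n_pulses - 1) / f
    a_soma <- soma_max * f / (f + f_half)
    a_dend <- if (stim_type == "dendritic") dend_gain * a_soma
              else if (f >= critical_freq) dend_gain * a_soma else 0
    for (k in seq_len(n_per_freq)) {
      id <- sprintf("%s_%gHz_%d", stim_type, f, k)
      trials[[length(trials) + 1]] <- exvivo_trial(
        soma = make_trace(a_soma, stim_end, "soma", paste0(id, "_soma")),
        dendrite = make_trace(a_dend, stim_end, "tuft", paste0(id, "_dend")),
        stim_type = stim_type, freq = f, n_pulses = n_pulses,
        stim_offset = stim_end, n_ap = n_pulses)
    }
  }
  sham_offset <- baseline_s + (n_pulses - 1) / stats::median(freqs)
  for (k in seq_len(n_sham)) {
    id <- sprintf("sham_%d", k)
    trials[[length(trials) + 1]] <- exvivo_trial(
      soma = make_trace(0, sham_offset, "soma", paste0(id, "_soma")),
      dendrite = make_trace(0, sham_offset, "tuft", paste0(id, "_dend")),
      stim_type = "sham", stim_offset = sham_offset, n_ap = 0L)
  }
  trials
}

#' Raw post-stimulation peak of one trial
#'
#' Converts the compartment trace to dF/F0 with the pre-stimulus baseline
#' (see [compute_dff_exvivo()]) and returns the maximum within `window_s`
#' seconds after stimulation cessation.
#'
#' @param trial an [exvivo_trial()].
#' @param compartment `"soma"` or `"dendrite"`.
#' @param window_s peak-search window after stimulation offset, seconds
#'   (default 1).
#' @param baseline_s pre-stimulus baseline length, seconds.
#' @param f_background background fluorescence.
#' @return peak dF/F0 in the window.
#' @export
exvivo_peak <- function(trial, compartment = c("soma", "dendrite"),
                        window_s = 1, baseline_s = 1, f_background = 0) {
  compartment <- match.arg(compartment)
  tr <- if (compartment == "soma") trial$soma else trial$dendrite
  dff <- compute_dff_exvivo(tr, baseline_window = c(0, baseline_s),
                            f_background = f_background)
  tt <- trace_times(dff)
  idx <- which(tt >= trial$stim_offset & tt <= trial$stim_offset + window_s)
  if (length(idx) == 0) stop("peak window contains no samples")
  max(dff$values[idx])
}

#' Leave-one-out sham null distribution
#'
#' Each sham peak is re-expressed against the mean of the remaining sham
#' peaks, giving the null distribution of null-subtracted amplitudes
#' expected in the absence of a stimulus.
#'
#' @param sham_peaks numeric vector of raw sham peaks (at least 3).
#' @return numeric vector, same length: `p_i - mean(p_{-i})`.
#' @export
exvivo_null <- function(sham_peaks) {
  n <- length(sham_peaks)
  if (n < 3) stop("need at least 3 sham trials to build the null")
  vapply(seq_len(n), function(i)
    sham_peaks[i] - mean(sham_peaks[-i]), numeric(1))
}

#' Sham-calibrated event detection
#'
#' An amplitude counts as a detected calcium event when it exceeds
#' `multiplier` (default 2.8) standard deviations of the sham-derived null
#' distribution.
#'
#' @param amplitude null-subtracted amplitude(s).
#' @param null_dist null distribution from [exvivo_null()].
#' @param multiplier detection threshold in null-SD units.
#' @return logical vector.
#' @export
exvivo_detect <- function(amplitude, null_dist, multiplier = 2.8) {
  if (length(null_dist) < 3) stop("need at least 3 sham trials")
  s <- stats::sd(null_dist)
  if (!is.finite(s) || s <= 0) stop("degenerate null distribution (SD = 0)")
  amplitude > multiplier * s
}

#' Analyse a set of ex vivo trials against the sham null
#'
#' Computes per-trial raw peaks in soma and dendrite, standardises each
#' compartment to its maximum evoked signal, subtracts the mean sham peak,
#' builds the leave-one-out sham null, and applies the 2.8-SD detection
#' rule per compartment.
#'
#' @param trials list of [exvivo_trial()] (stimulation and sham mixed).
#' @param multiplier detection threshold in null-SD units (default 2.8).
#' @param window_s,baseline_s,f_background passed to [exvivo_peak()].
#' @return list with `trials` (data.frame: `stim_type`, `freq`,
#'   `soma_amplitude`, `dend_amplitude`, `soma_detected`, `dend_detected`)
#'   and `null` (per-compartment null distributions).
#' @export
exvivo_analysis <- function(trials, multiplier = 2.8, window_s = 1,
                            baseline_s = 1, f_background = 0) {
  is_sham <- vapply(trials, function(tr) tr$stim_type == "sham", logical(1))
  if (sum(is_sham) < 3) stop("need at least 3 sham trials")
  peaks <- function(compartment) vapply(trials, exvivo_peak, numeric(1),
                                        compartment = compartment,
                                        window_s = window_s,
                                        baseline_s = baseline_s,
                                        f_background = f_background)
  res <- list()
  for (cc in c("soma", "dendrite")) {
    p <- peaks(cc)
    scale <- max(abs(p))
    if (scale > 0) p <- p / scale
    null <- exvivo_null(p[is_sham])
    amp <- p - mean(p[is_sham])
    res[[cc]] <- list(amp = amp, null = null,
                      detected = exvivo_detect(amp, null, multiplier))
  }
  tab <- data.frame(
    stim_type = vapply(trials, function(tr) tr$stim_type, character(1)),
    freq = vapply(trials, function(tr) as.numeric(tr$freq), numeric(1)),
    soma_amplitude = res$soma$amp,
    dend_amplitude = res$dendrite$amp,
    soma_detected = res$soma$detected,
    dend_detected = res$dendrite$detected)
  list(trials = tab,
       null = list(soma = res$soma$null, dendrite = res$dendrite$null))
}

#' Proportion of compartment-specific detections per stimulation group
#'
#' @param analysis result of [exvivo_analysis()] (or its `trials` table).
#' @return data.frame per (stim_type, freq): trial count, fraction of
#'   trials detected only in the soma, only in the dendrite, and in both.
#'   Sham trials form their own group (`freq = NA`).
#' @export
compartment_specific_exvivo <- function(analysis) {
  tab <- if (is.data.frame(analysis)) analysis else analysis$trials
  key <- paste(tab$stim_type, tab$freq, sep = "@")
  out <- do.call(rbind, lapply(split(tab, key), function(g) {
    data.frame(stim_type = g$stim_type[1], freq = g$freq[1], n = nrow(g),
               soma_only = mean(g$soma_detected & !g$dend_detected),
               dend_only = mean(!g$soma_detected & g$dend_detected),
               both = mean(g$soma_detected & g$dend_detected))
  }))
  out <- out[order(out$stim_type, out$freq), ]
  rownames(out) <- NULL
  out
}
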