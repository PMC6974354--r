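# Shared helpers: hand-built containers and independent oracles used to
# cross-check the pipeline's operations.

# Build an event_series directly from times/amplitudes, bypassing detection.
make_events <- function(times, amplitudes = rep(1, length(times)),
                        compartment = "soma", id = "manual",
                        norm_max = NULL) {
  if (is.null(norm_max)) norm_max <- if (length(amplitudes)) max(amplitudes) else NA_real_
  structure(list(
    events = data.frame(peak_time = times,
                        peak_index = rep(NA_integer_, length(times)),
                        value = amplitudes, amplitude = amplitudes,
                        norm_amplitude = if (length(amplitudes))
                          amplitudes / norm_max else numeric(0)),
    trace_id = id, neuron_id = NA_character_, compartment = compartment,
    fs = NA_real_, noise_sd = NA_real_, multiplier = NA_real_,
    norm_max = norm_max), class = "event_series")
}

make_dff <- function(values, fs, compartment = "soma", id = "dff") {
  new_trace(values, fs = fs, trace_id = id, compartment = compartment,
            kind = "dff")
}

# Exhaustive one-to-one assignment oracle: over all assignments of proximal
# events to admissible distal events, maximise the number of matches, then
# minimise the total |dt|. Only for small instances.
exhaustive_matching <- function(tp, td, before = 2, after = 1) {
  np <- length(tp)
  cand <- lapply(seq_len(np), function(i) {
    dt <- td - tp[i]
    which((dt >= -before & dt <= after) | (dt >= -after & dt <= before))
  })
  best <- list(count = -1L, cost = Inf)
  recurse <- function(i, used, count, cost) {
    if (i > np) {
      if (count > best$count ||
          (count == best$count && cost < best$cost - 1e-12))
        best <<- list(count = count, cost = cost)
      return(invisible())
    }
    recurse(i + 1L, used, count, cost)  # leave i unmatched
    for (j in cand[[i]]) {
      if (!used[j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L, cost + abs(td[j] - tp[i]))
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(td)), 0L, 0)
  best
}

# Textbook Pearson correlation, written out.
pearson_formula <- function(x, y) {
  n <- length(x)
  num <- sum((x - sum(x) / n) * (y - sum(y) / n))
  den <- sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
  num / den
}
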