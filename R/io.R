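# Columnar text I/O for traces, events and result tables.

TRACE_COLUMNS <- c("time_s", "value", "trace_id", "neuron_id", "compartment")

#' Read traces from a columnar CSV file
#'
#' Expects columns `time_s`, `value`, `trace_id`, `neuron_id`,
#' `compartment` (plus optional `kind`). Rows are grouped by `trace_id`;
#' the sampling rate is inferred from the median sample interval.
#'
#' @param path CSV file path.
#' @return named list of `trace` objects (empty list, with a warning, for
#'   an empty file).
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty trace file: ", path)
    return(list())
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRACE_COLUMNS, names(df))
  if (length(missing) > 0)
    stop("missing required columns: ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    warning("trace file has a header but no rows: ", path)
    return(list())
  }
  out <- lapply(split(df, df$trace_id), function(g) {
    g <- g[order(g$time_s), ]
    fs <- 1 / stats::median(diff(g$time_s))
    new_trace(g$value, fs = fs, t0 = g$time_s[1], trace_id = g$trace_id[1],
              neuron_id = as.character(g$neuron_id[1]),
              compartment = g$compartment[1],
              kind = if ("kind" %in% names(g)) g$kind[1] else "raw")
  })
  out[unique(df$trace_id)]
}

#' Write traces to a columnar CSV file
#'
#' @param traces a `trace` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(time_s = trace_times(tr), value = tr$values,
               trace_id = tr$trace_id, neuron_id = tr$neuron_id,
               compartment = tr$compartment, kind = tr$kind)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write detected events to CSV
#'
#' @param series an `event_series` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(series, path) {
  if (inherits(series, "event_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(es) {
    if (nrow(es$events) == 0) return(NULL)
    cbind(data.frame(trace_id = es$trace_id, compartment = es$compartment),
          es$events[, c("peak_time", "peak_index", "amplitude",
                        "norm_amplitude")])
  }))
  if (is.null(df))
    df <- data.frame(trace_id = character(0), compartment = character(0),
                     peak_time = numeric(0), peak_index = integer(0),
                     amplitude = numeric(0), norm_amplitude = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write behavioural labels to CSV
#'
#' @param labels a `behavior_labels`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_behavior <- function(labels, path) {
  tt <- labels$t0 + (seq_along(labels$state) - 1) / labels$fs
  utils::write.csv(data.frame(time_s = tt,
                              state = as.character(labels$state)),
                   path, row.names = FALSE)
  invisible(path)
}
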