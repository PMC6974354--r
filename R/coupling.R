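# Coincidence matching across compartment pairs and coupling statistics.

event_table <- function(x, side) {
  if (inherits(x, "event_series")) return(x$events)
  if (is.numeric(x))
    return(data.frame(peak_time = as.numeric(x), peak_index = NA_integer_,
                      value = NA_real_, amplitude = NA_real_,
                      norm_amplitude = NA_real_))
  stop(sprintf("%s must be an event_series or a numeric vector of times",
               side))
}

#' Match events across a proximal-distal compartment pair
#'
#' One-to-one coincidence matching with an asymmetric window: an event in
#' one compartment is a candidate coincidence for a reference event in the
#' other if it lies within `before` seconds before to `after` seconds after
#' the reference peak. Candidates are collected from both reference sides
#' (so the admissible lag is `[-before, before]` when `after <= before`),
#' globally ordered by |dt| and matched greedily, each event participating
#' in at most one match. No matched pair can be further apart than `before`
#' seconds.
#'
#' @param proximal,distal `event_series` (see [detect_events()]) or sorted
#'   numeric vectors of peak times in seconds.
#' @param before window extent before the reference peak, seconds
#'   (default 2).
#' @param after window extent after the reference peak, seconds (default 1).
#' @return object of class `"event_matching"`: data.frame `matches`
#'   (`prox_index`, `dist_index`, `prox_time`, `dist_time`, `dt`,
#'   amplitudes), integer vectors `proximal_only` and `distal_only`
#'   (unmatched event indices), and the window.
#' @export
match_events <- function(proximal, distal, before = 2, after = 1) {
  pe <- event_table(proximal, "proximal")
  de <- event_table(distal, "distal")
  if (is.unsorted(pe$peak_time, strictly = FALSE) ||
      is.unsorted(de$peak_time, strictly = FALSE))
    stop("event series must be sorted by peak time")
  np <- nrow(pe); nd <- nrow(de)
  cand <- NULL
  if (np > 0 && nd > 0) {
    dt <- outer(pe$peak_time, de$peak_time, function(p, d) d - p)
    # admissible from the proximal reference: dt in [-before, after];
    # admissible from the distal reference:   dt in [-after, before]
    ok <- (dt >= -before & dt <= after) | (dt >= -after & dt <= before)
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx) > 0)
      cand <- data.frame(i = idx[, 1], j = idx[, 2],
                         dt = dt[idx])
  }
  matches <- data.frame(prox_index = integer(0), dist_index = integer(0),
                        prox_time = numeric(0), dist_time = numeric(0),
                        dt = numeric(0), prox_amplitude = numeric(0),
                        dist_amplitude = numeric(0),
                        prox_norm = numeric(0), dist_norm = numeric(0))
  if (!is.null(cand)) {
    cand <- cand[order(abs(cand$dt), cand$i, cand$j), , drop = FALSE]
    used_p <- logical(np); used_d <- logical(nd)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!used_p[i] && !used_d[j]) {
        used_p[i] <- TRUE; used_d[j] <- TRUE; keep[k] <- TRUE
      }
    }
    m <- cand[keep, , drop = FALSE]
    m <- m[order(m$i), , drop = FALSE]
    matches <- data.frame(prox_index = m$i, dist_index = m$j,
                          prox_time = pe$peak_time[m$i],
                          dist_time = de$peak_time[m$j],
                          dt = m$dt,
                          prox_amplitude = pe$amplitude[m$i],
                          dist_amplitude = de$amplitude[m$j],
                          prox_norm = pe$norm_amplitude[m$i],
                          dist_norm = de$norm_amplitude[m$j])
  }
  structure(list(matches = matches,
                 proximal_only = setdiff(seq_len(np), matches$prox_index),
                 distal_only = setdiff(seq_len(nd), matches$dist_index),
                 n_proximal = np, n_distal = nd,
                 before = before, after = after),
            class = "event_matching")
}

#' @export
print.event_matching <- function(x, ...) {
  cat(sprintf("<event_matching> %d matched, %d proximal-only, %d distal-only (window -%g/+%g s)\n",
              nrow(x$matches), length(x$proximal_only),
              length(x$distal_only), x$before, x$after))
  invisible(x)
}

# max - min of a dF/F0 trace in a window of width window_s centred on t.
range_readout <- function(dff, t, window_s = 3) {
  tt <- trace_times(dff)
  idx <- which(tt >= t - window_s / 2 & tt <= t + window_s / 2)
  if (length(idx) == 0) return(NA_real_)
  diff(range(dff$values[idx]))
}

#' Coupling statistics for one compartment pair
#'
#' Matches the two event series, then builds the amplitude-pair table used
#' for the Pearson correlation: matched events contribute their two peak
#' amplitudes; for compartment-specific events the silent side contributes
#' the max-minus-min of its dF/F0 trace in a 3 s window centred on the
#' detected peak.
#'
#' @param prox_events,dist_events `event_series` for the proximal and
#'   distal compartment.
#' @param prox_dff,dist_dff the corresponding dF/F0 traces (needed for the
#'   silent-side read-out of compartment-specific events); optional when
#'   every event is matched.
#' @param before,after matching window, seconds.
#' @param readout_window_s width of the centred read-out window, seconds.
#' @return object of class `"pair_coupling"`: the `event_matching`, the
#'   amplitude-pair table `pairs` (`prox`, `dist`, `matched`, normalised
#'   columns), Pearson `r`, and `frequency_ratio` = n_distal / n_proximal.
#' @export
pair_coupling <- function(prox_events, dist_events, prox_dff = NULL,
                          dist_dff = NULL, before = 2, after = 1,
                          readout_window_s = 3) {
  matching <- match_events(prox_events, dist_events, before, after)
  pe <- prox_events$events; de <- dist_events$events
  m <- matching$matches
  pairs <- data.frame(prox = m$prox_amplitude, dist = m$dist_amplitude,
                      prox_norm = m$prox_norm, dist_norm = m$dist_norm,
                      matched = rep(TRUE, nrow(m)))
  for (i in matching$proximal_only) {
    ro <- if (is.null(dist_dff)) NA_real_ else
      range_readout(dist_dff, pe$peak_time[i], readout_window_s)
    pairs <- rbind(pairs, data.frame(
      prox = pe$amplitude[i], dist = ro,
      prox_norm = pe$norm_amplitude[i],
      dist_norm = if (is.null(dist_dff) || is.null(dist_events$norm_max))
        NA_real_ else ro / dist_events$norm_max,
      matched = FALSE))
  }
  for (j in matching$distal_only) {
    ro <- if (is.null(prox_dff)) NA_real_ else
      range_readout(prox_dff, de$peak_time[j], readout_window_s)
    pairs <- rbind(pairs, data.frame(
      prox = ro, dist = de$amplitude[j],
      prox_norm = if (is.null(prox_dff) || is.null(prox_events$norm_max))
        NA_real_ else ro / prox_events$norm_max,
      dist_norm = de$norm_amplitude[j],
      matched = FALSE))
  }
  ok <- stats::complete.cases(pairs[, c("prox", "dist")])
  r <- if (sum(ok) >= 3 && stats::sd(pairs$prox[ok]) > 0 &&
           stats::sd(pairs$dist[ok]) > 0)
    stats::cor(pairs$prox[ok], pairs$dist[ok])
  else NA_real_
  structure(list(matching = matching, pairs = pairs, r = r,
                 frequency_ratio = if (matching$n_proximal > 0)
                   matching$n_distal / matching$n_proximal else NA_real_,
                 n_proximal = matching$n_proximal,
                 n_distal = matching$n_distal,
                 prox_events = prox_events, dist_events = dist_events),
            class = "pair_coupling")
}

#' @export
print.pair_coupling <- function(x, ...) {
  cat(sprintf("<pair_coupling> r = %.3f over %d amplitude pairs; frequency ratio %.3f\n",
              x$r, nrow(x$pairs), x$frequency_ratio))
  invisible(x)
}

#' Pearson correlation of paired transient amplitudes
#'
#' @param pair a [pair_coupling()].
#' @return Pearson r over all amplitude pairs (matched and
#'   compartment-specific). Fewer than 3 complete pairs is an error: the
#'   correlation is then undefined, which is distinct from r = 0.
#' @export
pair_correlation <- function(pair) {
  if (!inherits(pair, "pair_coupling")) stop("pair must be a pair_coupling")
  ok <- stats::complete.cases(pair$pairs[, c("prox", "dist")])
  if (sum(ok) < 3)
    stop("fewer than 3 amplitude pairs: correlation undefined")
  stats::cor(pair$pairs$prox[ok], pair$pairs$dist[ok])
}

#' Permutation null for the amplitude correlation
#'
#' Shuffles the order of the amplitudes on the distal side of the pair
#' table and recomputes the Pearson correlation per permutation, breaking
#' the event-wise pairing while preserving both marginal amplitude
#' distributions. The null is centred at zero.
#'
#' @param pair a [pair_coupling()].
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @param permutations optional list of explicit index permutations (each a
#'   permutation of the pair indices), overriding random shuffling.
#' @return list with `r_values` (length `n_perm`), `mean` and the observed
#'   `r`.
#' @export
shuffle_null <- function(pair, n_perm = 1000, seed = NULL,
                         permutations = NULL) {
  if (!inherits(pair, "pair_coupling")) stop("pair must be a pair_coupling")
  if (n_perm < 1) stop("n_perm must be >= 1")
  ok <- stats::complete.cases(pair$pairs[, c("prox", "dist")])
  x <- pair$pairs$prox[ok]; y <- pair$pairs$dist[ok]
  if (length(x) < 3) stop("fewer than 3 amplitude pairs")
  if (!is.null(seed)) set.seed(seed)
  r_values <- if (!is.null(permutations))
    vapply(permutations, function(p) stats::cor(x, y[p]), numeric(1))
  else vapply(seq_len(n_perm), function(k)
    stats::cor(x, sample(y)), numeric(1))
  list(r_values = r_values, mean = mean(r_values),
       r = stats::cor(x, y))
}

#' Proportion of compartment-specific events by amplitude bin
#'
#' For each bin of normalised amplitude (width 0.05 on \[0, 1\] by default)
#' and each pair, computes the proportion of proximal events with no
#' matched distal event (and symmetrically for distal events). Across
#' pairs, per-bin proportions are combined as a weighted mean with weights
#' equal to the per-pair event count in the bin, with a weighted SEM.
#' Bins with no events are reported as `NA`, not zero.
#'
#' @param pairs a [pair_coupling()] or list of them.
#' @param bin_width amplitude bin width (default 0.05). Bins are half-open
#'   `[k w, (k+1) w)`; the final bin is closed at 1.
#' @return data.frame of class `"binned_specificity"` with columns
#'   `bin_lo`, `bin_hi`, `prox_specific`, `prox_sem`, `prox_n`,
#'   `dist_specific`, `dist_sem`, `dist_n`.
#' @export
binned_specificity <- function(pairs, bin_width = 0.05) {
  if (inherits(pairs, "pair_coupling")) pairs <- list(pairs)
  if (length(pairs) == 0) stop("need at least one pair")
  edges <- seq(0, 1, by = bin_width)
  nb <- length(edges) - 1
  bin_of <- function(a) pmin(pmax(floor(a / bin_width) + 1L, 1L), nb)
  side_stats <- function(get_amp, get_specific) {
    p <- matrix(NA_real_, length(pairs), nb)
    w <- matrix(0, length(pairs), nb)
    for (k in seq_along(pairs)) {
      amp <- get_amp(pairs[[k]])
      spec <- get_specific(pairs[[k]])
      if (length(amp) == 0) next
      b <- bin_of(amp)
      for (bb in unique(b)) {
        sel <- b == bb
        p[k, bb] <- mean(spec[sel])
        w[k, bb] <- sum(sel)
      }
    }
    prop <- sem <- rep(NA_real_, nb)
    n <- colSums(w)
    for (bb in seq_len(nb)) {
      use <- which(w[, bb] > 0)
      if (length(use) == 0) next
      wt <- w[use, bb]; pv <- p[use, bb]
      prop[bb] <- sum(wt * pv) / sum(wt)
      if (length(use) > 1) {
        v <- sum(wt * (pv - prop[bb])^2) / sum(wt) *
          length(use) / (length(use) - 1)
        sem[bb] <- sqrt(v / length(use))
      } else sem[bb] <- NA_real_
    }
    list(prop = prop, sem = sem, n = n)
  }
  px <- side_stats(
    function(pr) pr$prox_events$events$norm_amplitude,
    function(pr) !(seq_len(pr$n_proximal) %in% pr$matching$matches$prox_index))
  dx <- side_stats(
    function(pr) pr$dist_events$events$norm_amplitude,
    function(pr) !(seq_len(pr$n_distal) %in% pr$matching$matches$dist_index))
  structure(data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                       prox_specific = px$prop, prox_sem = px$sem,
                       prox_n = px$n,
                       dist_specific = dx$prop, dist_sem = dx$sem,
                       dist_n = dx$n),
            class = c("binned_specificity", "data.frame"))
}

#' Distal/proximal event-frequency ratios
#'
#' @param pairs a [pair_coupling()] or list of them.
#' @return numeric vector of per-pair ratios n_distal / n_proximal. A pair
#'   with zero proximal events is an error (the ratio is undefined).
#' @export
frequency_attenuation <- function(pairs) {
  if (inherits(pairs, "pair_coupling")) pairs <- list(pairs)
  vapply(pairs, function(pr) {
    if (pr$n_proximal == 0)
      stop("zero proximal events: frequency ratio undefined")
    pr$n_distal / pr$n_proximal
  }, numeric(1))
}

#' Compound loss along a chain of segments
#'
#' Given per-segment fractional losses of event frequency, the compound
#' loss over the chain is `1 - prod(1 - loss_i)`: chaining the per-segment
#' frequency decreases from soma to distal tuft (14%, 8%, 24%) yields a
#' total loss of about 40%.
#'
#' @param segment_losses fractional losses in `[0, 1]`, ordered from
#'   proximal to distal.
#' @return compound fractional loss in `[0, 1]`.
#' @export
chain_attenuation <- function(segment_losses) {
  if (any(segment_losses < 0 | segment_losses > 1))
    stop("losses must lie in [0, 1]")
  1 - prod(1 - segment_losses)
}

#' Containment width of coincidence intervals
#'
#' The empirical distribution of time lags between matched events is
#' centred near zero; the interval mean +/- 1 SD contains ~95% of matched
#' lags, so its width is `2 * sd`. With the observed lag SD of 0.28 s this
#' gives 0.56 s.
#'
#' @param sd_dt standard deviation of matched time lags, seconds.
#' @return width of the +/- 1 SD containment interval, seconds.
#' @export
containment_width <- function(sd_dt) 2 * sd_dt

#' Lag statistics of a matching
#'
#' @param x an `event_matching` or `pair_coupling`.
#' @return list with `mean`, `sd`, `max_abs` and `width` (the +/- 1 SD
#'   containment width) of the matched lags.
#' @export
match_interval_stats <- function(x) {
  if (inherits(x, "pair_coupling")) x <- x$matching
  dt <- x$matches$dt
  list(mean = mean(dt), sd = stats::sd(dt),
       max_abs = if (length(dt)) max(abs(dt)) else NA_real_,
       width = containment_width(stats::sd(dt)))
}

#' Residuals from a robust amplitude-amplitude regression
#'
#' Fits a robust linear regression (iteratively reweighted least squares
#' with Tukey bisquare weights, tuning constant 4.685) of distal on
#' proximal normalised amplitudes for each pair, and returns each point's
#' vertical distance from the fit. Condition labels (e.g. darkness/gratings
#' x stationary/locomotion) group the residuals into per-condition
#' empirical cumulative distributions.
#'
#' @param pairs a [pair_coupling()] or list of them.
#' @param conditions optional list (parallel to `pairs`) of per-amplitude-
#'   pair condition labels, or a single vector when one pair is given.
#' @param use_norm regress normalised (`TRUE`, default) or raw amplitudes.
#' @return list with `residuals` (data.frame: `pair`, `prox`, `dist`,
#'   `fitted`, `residual`, `condition`), per-pair `fits` (intercept,
#'   slope), and `ecdf` (named list of [stats::ecdf()] per condition).
#' @export
residual_analysis <- function(pairs, conditions = NULL, use_norm = TRUE) {
  if (inherits(pairs, "pair_coupling")) {
    pairs <- list(pairs)
    if (!is.null(conditions) && !is.list(conditions))
      conditions <- list(conditions)
  }
  out <- NULL
  fits <- data.frame(pair = integer(0), intercept = numeric(0),
                     slope = numeric(0))
  for (k in seq_along(pairs)) {
    tab <- pairs[[k]]$pairs
    x <- if (use_norm) tab$prox_norm else tab$prox
    y <- if (use_norm) tab$dist_norm else tab$dist
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need at least 3 amplitude pairs per fit")
    if (stats::sd(x) < 1e-12)
      stop("degenerate proximal amplitude variance: fit rejected")
    fit <- withCallingHandlers(
      MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                maxit = 200, acc = 1e-8),
      warning = function(w) {
        # an exact fit drives the residual scale to zero, where the IRLS
        # convergence test cannot fire even though the fit is final
        if (grepl("failed to converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    res <- y - (coef(fit)[1] + coef(fit)[2] * x)
    if (stats::median(abs(res)) > 1e-8 && fit$converged %in% FALSE)
      warning("robust regression did not converge for pair ", k)
    cond <- if (!is.null(conditions)) as.character(conditions[[k]][ok])
            else rep(NA_character_, length(x))
    out <- rbind(out, data.frame(pair = k, prox = x, dist = y,
                                 fitted = y - res, residual = unname(res),
                                 condition = cond))
    fits <- rbind(fits, data.frame(pair = k,
                                   intercept = unname(coef(fit)[1]),
                                   slope = unname(coef(fit)[2])))
  }
  ecdfs <- if (!is.null(conditions))
    lapply(split(out$residual, out$condition), stats::ecdf)
  else list(all = stats::ecdf(out$residual))
  list(residuals = out, fits = fits, ecdf = ecdfs)
}
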