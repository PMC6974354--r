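test_that("noise SD estimation removes DC, scales linearly, matches spectrum", {
  expect_lt(estimate_noise_sd(make_dff(rep(0.4, 300), 5)), 1e-10)

  set.seed(2)
  x <- rnorm(2000)
  s1 <- estimate_noise_sd(make_dff(x, 5))
  s3 <- estimate_noise_sd(make_dff(3 * x, 5))
  expect_equal(s3, 3 * s1, tolerance = 1e-12)

  # spectral oracle: ideal frequency-domain high-pass at 0.6 Hz
  set.seed(3)
  n <- 20000; fs <- 5
  w <- rnorm(n)
  X <- fft(w)
  fr <- (seq_len(n) - 1) / n * fs
  fr <- pmin(fr, fs - fr)
  X[fr < 0.6] <- 0
  oracle <- sd(Re(fft(X, inverse = TRUE)) / n)
  est <- estimate_noise_sd(make_dff(w, fs))
  expect_lt(abs(est - oracle) / oracle, 0.05)

  expect_error(estimate_noise_sd(make_dff(rnorm(10), 5)), "filter lengths")
})

test_that("detection is empty on a zero trace and exact on one clean transient", {
  expect_equal(nrow(detect_events(make_dff(rep(0, 200), 5),
                                  noise_sd = 0.01)$events), 0)

  fs <- 20
  tt <- seq(0, 10, by = 1 / fs)
  dff <- 0.5 * calcium_kernel(tt - 2, 0.18, 1.0)
  es <- detect_events(make_dff(dff, fs), noise_sd = 0.05)  # peak = 10 x SD
  expect_equal(nrow(es$events), 1)
  expect_equal(es$events$peak_index, which.max(dff))
  expect_equal(es$events$amplitude, max(dff))  # pre-peak minimum is 0
  expect_equal(es$events$norm_amplitude, 1)
})

test_that("detection equals a brute-force local-maximum scan on noise", {
  set.seed(13)
  x <- rnorm(10000)
  fs <- 5; noise_sd <- 1; mult <- 2.8
  es <- detect_events(make_dff(x, fs), noise_sd = noise_sd,
                      multiplier = mult)
  brute <- integer(0)
  for (i in 2:(length(x) - 1))
    if (x[i] > x[i - 1] && x[i] > x[i + 1] && x[i] > mult * noise_sd)
      brute <- c(brute, i)
  expect_identical(es$events$peak_index, brute)
})

test_that("plateaus yield their left-most sample as the peak", {
  x <- c(0, 0, 1, 1, 1, 0, 0, 2, 0)
  es <- detect_events(make_dff(x, 5), noise_sd = 0.1)
  expect_equal(es$events$peak_index, c(3L, 8L))
})

test_that("amplitude uses the backward-window minimum and is non-negative", {
  fs <- 5
  # decaying staircase: second peak rides on the tail of the first
  tt <- seq(0, 20, by = 1 / fs)
  dff <- 0.8 * calcium_kernel(tt - 5, 0.18, 1.0) +
         0.5 * calcium_kernel(tt - 7.5, 0.18, 1.0)
  es <- detect_events(make_dff(dff, fs), noise_sd = 0.02)
  expect_true(all(es$events$amplitude >= 0))
  expect_true(all(es$events$amplitude <= es$events$value + 1e-12))
  # second amplitude is measured from its own local minimum, not zero
  if (nrow(es$events) == 2)
    expect_lt(es$events$amplitude[2], es$events$value[2])
})

test_that("detection is deterministic and translation-equivariant", {
  set.seed(6)
  fs <- 5
  x <- as.numeric(stats::filter(rnorm(2000), rep(1 / 3, 3), circular = TRUE))
  e1 <- detect_events(make_dff(x, fs), noise_sd = 0.5)
  e2 <- detect_events(make_dff(x, fs), noise_sd = 0.5)
  expect_identical(e1$events, e2$events)
  shift <- 100L
  e3 <- detect_events(make_dff(c(rep(0, shift), x), fs), noise_sd = 0.5)
  inner <- e3$events$peak_index > shift + 1
  expect_equal(e3$events$peak_index[inner], e1$events$peak_index + shift)
  expect_equal(e3$events$peak_time[inner],
               e1$events$peak_time + shift / fs)
})

test_that("noiseless traces give perfect recall and precision vs ground truth", {
  cfg <- synth_config(duration = 600, fs = 4.8, soma_event_rate = 3,
                      tuft_initiated_rate = 0, noise_sd = 0,
                      attenuation = attenuation_constant(1), seed = 4)
  sim <- generate_neuron(cfg, 1)
  truth_t <- sim$truth$events$time
  # this realisation has well-separated events, a precondition for
  # one-peak-per-transient detection
  expect_gt(min(diff(truth_t)), 2.5)
  d <- compute_dff(sim$traces$soma)
  es <- detect_events(d, noise_sd = 0.01)
  expect_equal(nrow(es$events), length(truth_t))
  expect_true(all(abs(es$events$peak_time -
                        (truth_t + kernel_peak_time(0.18, 1))) < 0.5))
})

test_that("threshold sweep is monotone and nested", {
  set.seed(17)
  fs <- 5
  tt <- seq(0, 300, by = 1 / fs)
  dff <- rnorm(length(tt), 0, 0.02)
  for (t0 in seq(10, 290, by = 10))
    dff <- dff + runif(1, 0.03, 0.4) * calcium_kernel(tt - t0, 0.18, 1)
  d <- make_dff(dff, fs)
  ns <- 0.02
  sw <- threshold_sweep(d, noise_sd = ns, multipliers = c(1.96, 2.8, 3.64))
  counts <- vapply(sw, function(es) nrow(es$events), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(sw[["2.80"]]$events,
                   detect_events(d, noise_sd = ns, multiplier = 2.8)$events)
  expect_true(all(sw[["3.64"]]$events$peak_index %in%
                    sw[["2.80"]]$events$peak_index))
  expect_error(threshold_sweep(d, noise_sd = ns, multipliers = numeric(0)),
               "non-empty")
})
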