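test_that("zero event rates give baseline-plus-noise traces and empty truth", {
  cfg <- synth_config(duration = 120, soma_event_rate = 0,
                      tuft_initiated_rate = 0, noise_sd = 0.02, seed = 5)
  sim <- generate_neuron(cfg, 1)
  expect_equal(nrow(sim$truth$events), 0)
  for (tr in sim$traces) {
    expect_equal(mean(tr$values), cfg$baseline_f0,
                 tolerance = 4 * 0.02 / sqrt(length(tr$values)))
    expect_lt(sd(tr$values), 2 * 0.02 * cfg$baseline_f0)
  }
})

test_that("a single noiseless impulse reproduces the closed-form kernel peak", {
  rise <- 0.18; decay <- 1.0
  # closed-form peak location of exp(-t/decay) - exp(-t/rise)
  tstar <- rise * decay / (decay - rise) * log(decay / rise)
  peak_raw <- exp(-tstar / decay) - exp(-tstar / rise)
  expect_equal(kernel_peak_time(rise, decay), tstar)
  expect_equal(max(calcium_kernel(seq(0, 5, 1e-4), rise, decay)), 1,
               tolerance = 1e-6)
  expect_equal(calcium_kernel(tstar, rise, decay), 1, tolerance = 1e-12)
  expect_equal(kernel_peak(rise, decay), peak_raw)

  # rendered trace: amplitude a transient peaks at a x (sampled kernel max)
  a <- 0.7; fs <- 120
  tt <- seq(0, 5, by = 1 / fs)
  dff <- a * calcium_kernel(tt - 1, rise, decay)
  expect_equal(max(dff), a * max(calcium_kernel(tt - 1, rise, decay)))
  expect_equal(max(dff), a, tolerance = 1e-3)  # dense sampling hits the peak
})

test_that("lossless propagation puts every somatic event in every compartment", {
  cfg <- synth_config(duration = 300, soma_event_rate = 10,
                      tuft_initiated_rate = 0,
                      attenuation = attenuation_constant(1), seed = 11)
  sim <- generate_neuron(cfg, 1)
  expect_true(all(sim$truth$presence))
  counts <- colSums(sim$truth$presence)
  expect_true(all(counts == counts["soma"]))
  expect_equal(unname(counts["tuft"] / counts["soma"]), 1)
})

test_that("identical config and seed give bit-identical traces and truth", {
  cfg <- synth_config(duration = 60, seed = 123)
  a <- generate_neuron(cfg, 2)
  b <- generate_neuron(cfg, 2)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$truth$presence, b$truth$presence)
  for (nm in names(a$traces))
    expect_identical(a$traces[[nm]]$values, b$traces[[nm]]$values)
  # a different neuron id gives a different stream
  c <- generate_neuron(cfg, 3)
  expect_false(identical(a$traces$soma$values, c$traces$soma$values))
})

test_that("distal events never outnumber proximal plus tuft-initiated ones", {
  cfg <- synth_config(duration = 400, soma_event_rate = 8,
                      tuft_initiated_rate = 1, seed = 9)
  for (nid in 1:5) {
    tr <- generate_neuron(cfg, nid)$truth
    n_tuft_init <- sum(tr$events$origin == "tuft")
    counts <- colSums(tr$presence)
    comps <- cfg$compartments
    for (k in 2:length(comps))
      expect_lte(counts[comps[k]], counts[comps[k - 1]] + n_tuft_init)
    # somatofugal flags are nested for somatic events
    som <- tr$events$origin == "soma"
    for (k in 2:length(comps))
      expect_true(all(tr$presence[som, comps[k]] <=
                        tr$presence[som, comps[k - 1]]))
  }
})

test_that("empirical propagation matches configured mean survival within 3 SE", {
  cfg <- synth_config(duration = 3000, soma_event_rate = 30,
                      tuft_initiated_rate = 0, seed = 21)
  truth <- generate_neuron(cfg, 1)$truth
  n_soma <- sum(truth$presence[, "soma"])
  expect_gt(n_soma, 1000)
  p_exp <- mean_survival(cfg, "pTrunk")
  p_obs <- sum(truth$presence[, "pTrunk"]) / n_soma
  se <- sqrt(p_exp * (1 - p_exp) / n_soma)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("non-finite or invalid config values are rejected with the field name", {
  expect_error(synth_config(noise_sd = NaN), "noise_sd")
  expect_error(synth_config(duration = Inf), "duration")
  expect_error(synth_config(soma_event_rate = -1), "soma_event_rate")
  expect_error(synth_config(kernel_rise = 2, kernel_decay = 1), "kernel")
  expect_error(synth_config(tuft_soma_survival = 1.5), "tuft_soma_survival")
})

test_that("speed generator follows the bout specification", {
  sp <- generate_speed(30, 10)
  expect_true(all(sp$speed == 0))

  sp <- generate_speed(30, 10, data.frame(start = 10, stop = 20, speed = 5))
  tt <- trace_times(sp)
  expect_true(all(sp$speed[tt >= 10 & tt < 20] == 5))
  expect_true(all(sp$speed[tt < 10 | tt >= 20] == 0))

  a <- generate_speed(30, 10, data.frame(start = 10, stop = 20, speed = 5),
                      jitter_sd = 0.5, seed = 77)
  b <- generate_speed(30, 10, data.frame(start = 10, stop = 20, speed = 5),
                      jitter_sd = 0.5, seed = 77)
  expect_identical(a$speed, b$speed)

  expect_error(generate_speed(30, 10,
    data.frame(start = c(5, 8), stop = c(10, 12), speed = c(1, 2))),
    "overlap")
})

test_that("tuned gains invert the OSI formula", {
  sched <- stim_schedule(seq(0, by = 7, length.out = 8), seq(0, 315, by = 45))
  g0 <- generate_tuned_responses(sched, 45, 0)
  expect_true(all(abs(g0 - g0[1]) < 1e-12))

  g1 <- generate_tuned_responses(sched, 45, 1)
  curve <- attr(g1, "curve")
  expect_equal(unname(curve[["135"]]), 0)

  g5 <- generate_tuned_responses(sched, 0, 0.5, gain = 1)
  curve <- attr(g5, "curve")
  expect_equal(unname(curve[["90"]]), 1 / 3, tolerance = 1e-12)
  expect_equal((1 - 1 / 3) / (1 + 1 / 3), 0.5)
  o <- osi(curve)
  expect_equal(o$osi, 0.5, tolerance = 1e-12)
  expect_equal(o$preferred, 0)
})
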