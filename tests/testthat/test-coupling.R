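test_that("identical event lists match completely at zero lag", {
  t <- c(5, 12, 30, 44.5, 60)
  m <- match_events(make_events(t), make_events(t))
  expect_equal(nrow(m$matches), 5)
  expect_true(all(m$matches$dt == 0))
  expect_length(m$proximal_only, 0)
  expect_length(m$distal_only, 0)
})

test_that("events further apart than 2 s are never matched", {
  m <- match_events(make_events(10.0), make_events(12.5))
  expect_equal(nrow(m$matches), 0)
  expect_equal(m$proximal_only, 1L)
  expect_equal(m$distal_only, 1L)
  # the asymmetric window: distal 1.5 s after proximal IS matched (symmetric
  # pass from the distal reference), distal 2.1 s after is not
  expect_equal(nrow(match_events(make_events(10), make_events(11.5))$matches), 1)
  expect_equal(nrow(match_events(make_events(10), make_events(12.1))$matches), 0)
})

test_that("unsorted series are rejected", {
  expect_error(match_events(make_events(c(5, 3)), make_events(4)), "sorted")
})

test_that("matching equals the exhaustive assignment oracle on small instances", {
  set.seed(41)
  for (rep in 1:20) {
    # well-separated proximal events with jittered distal partners plus
    # extra distal events far from every proximal one
    np <- sample(3:7, 1)
    tp <- cumsum(runif(np, 3.5, 8))
    keep <- runif(np) < 0.8
    td <- tp[keep] + runif(sum(keep), -0.4, 0.4)
    extra <- max(tp) + 10 + cumsum(runif(sample(1:3, 1), 3, 6))
    td <- sort(c(td, extra))
    m <- match_events(make_events(tp), make_events(td))
    oracle <- exhaustive_matching(tp, td)
    expect_equal(nrow(m$matches), oracle$count)
    expect_equal(sum(abs(m$matches$dt)), oracle$cost, tolerance = 1e-9)
    expect_lte(max(abs(m$matches$dt)), 2)
  }
})

test_that("the larger jittered instance matches the brute-force assignment", {
  set.seed(55)
  tp <- cumsum(runif(50, 3, 6))
  td <- sort(c(tp + runif(50, -0.4, 0.4),
               max(tp) + 20 + cumsum(runif(10, 3, 6))))
  m <- match_events(make_events(tp), make_events(td))
  expect_equal(nrow(m$matches), 50)
  # with separation > 2.8 s every proximal event has exactly one candidate,
  # so the greedy result is the unique optimal assignment
  expect_true(all(abs(m$matches$dt) <= 0.4 + 1e-9))
  expect_length(m$distal_only, 10)
})

test_that("conservation: matched plus compartment-specific equals totals", {
  set.seed(19)
  tp <- sort(runif(40, 0, 300))
  td <- sort(runif(25, 0, 300))
  m <- match_events(make_events(tp), make_events(td))
  expect_equal(nrow(m$matches) + length(m$proximal_only), 40)
  expect_equal(nrow(m$matches) + length(m$distal_only), 25)
  expect_true(all(!duplicated(m$matches$prox_index)))
  expect_true(all(!duplicated(m$matches$dist_index)))
})

test_that("pair correlation matches the textbook formula and affine limit", {
  t <- seq(10, by = 10, length.out = 5)
  pc <- pair_coupling(make_events(t, c(1, 2, 3, 4, 5)),
                      make_events(t, c(2, 1, 4, 3, 6)))
  expect_equal(pair_correlation(pc),
               pearson_formula(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6)),
               tolerance = 1e-15)

  amps <- runif(20, 0.5, 3)
  t20 <- seq(5, by = 8, length.out = 20)
  pc2 <- pair_coupling(make_events(t20, amps), make_events(t20, 0.5 * amps))
  expect_equal(pair_correlation(pc2), 1, tolerance = 1e-12)

  set.seed(23)
  n <- 4000
  tn <- seq(5, by = 5, length.out = n)
  pc3 <- pair_coupling(make_events(tn, runif(n, 1, 2)),
                       make_events(tn, runif(n, 1, 2)))
  expect_lt(abs(pair_correlation(pc3)), 0.1)

  short <- pair_coupling(make_events(c(5, 10), c(1, 2)),
                         make_events(c(5, 10), c(1, 2)))
  expect_error(pair_correlation(short), "undefined")
})

test_that("compartment-specific events use the silent-side range read-out", {
  fs <- 5
  tt <- seq(0, 60, by = 1 / fs)
  # proximal has two transients; distal only the first
  prox_dff <- make_dff(0.8 * calcium_kernel(tt - 20, 0.18, 1) +
                       0.6 * calcium_kernel(tt - 40, 0.18, 1), fs)
  dist_dff <- make_dff(0.7 * calcium_kernel(tt - 20, 0.18, 1), fs, "tuft")
  pe <- detect_events(prox_dff, noise_sd = 0.02)
  de <- detect_events(dist_dff, noise_sd = 0.02)
  pc <- pair_coupling(pe, de, prox_dff, dist_dff)
  expect_equal(nrow(pc$matching$matches), 1)
  expect_length(pc$matching$proximal_only, 1)
  un <- pc$pairs[!pc$pairs$matched, ]
  t_spec <- pe$events$peak_time[pc$matching$proximal_only]
  idx <- which(tt >= t_spec - 1.5 & tt <= t_spec + 1.5)
  expect_equal(un$dist, diff(range(dist_dff$values[idx])))
})

test_that("shuffle null is centred at zero, seeded, and honours forced permutations", {
  set.seed(29)
  n <- 200
  amps <- rlnorm(n, 0, 0.5)
  t <- seq(5, by = 5, length.out = n)
  pc <- pair_coupling(make_events(t, amps), make_events(t, 0.8 * amps))
  expect_equal(pc$r, 1, tolerance = 1e-10)

  sn <- shuffle_null(pc, n_perm = 1, permutations = list(seq_len(n)))
  expect_equal(sn$r_values, pc$r)

  sn1 <- shuffle_null(pc, n_perm = 1000, seed = 101)
  sn2 <- shuffle_null(pc, n_perm = 1000, seed = 101)
  expect_identical(sn1$r_values, sn2$r_values)
  # permutation-null theory: mean r ~ 0 with SE ~ 1/sqrt(n-1) per draw
  se <- 1 / sqrt(n - 1) / sqrt(1000)
  expect_lt(abs(sn1$mean), 3 * se + 1e-3)
})

test_that("binned specificity is zero for lossless pairs and recovers a step rule", {
  n <- 500
  t <- seq(4, by = 4, length.out = n)
  amps <- seq(0.012, 1, length.out = n)
  lossless <- pair_coupling(make_events(t, amps), make_events(t, amps))
  bs <- binned_specificity(lossless)
  expect_true(all(bs$prox_specific[bs$prox_n > 0] == 0))
  expect_true(all(bs$dist_specific[bs$dist_n > 0] == 0))

  # step rule: every event below norm amplitude 0.3 attenuates, none above
  keep <- amps >= 0.3
  stepped <- pair_coupling(
    make_events(t, amps, norm_max = 1),
    make_events(t[keep], amps[keep], norm_max = 1))
  bs2 <- binned_specificity(stepped)
  lo <- bs2$bin_hi <= 0.3 & bs2$prox_n > 0
  hi <- bs2$bin_lo >= 0.3 & bs2$prox_n > 0
  expect_true(all(bs2$prox_specific[lo] == 1))
  expect_true(all(bs2$prox_specific[hi] == 0))

  # single pair: weighted mean equals the raw per-bin proportions
  one <- binned_specificity(list(stepped))
  expect_equal(one$prox_specific, bs2$prox_specific)
  # empty bins are missing, not zero
  expect_true(all(is.na(bs2$prox_specific[bs2$prox_n == 0])))
})

test_that("frequency ratios and compound chain attenuation", {
  t <- seq(5, by = 5, length.out = 20)
  pr <- pair_coupling(make_events(t), make_events(t[1:15]))
  expect_equal(frequency_attenuation(pr), 0.75)
  empty <- suppressWarnings(
    pair_coupling(make_events(numeric(0), numeric(0)), make_events(t[1:3])))
  expect_error(frequency_attenuation(empty), "undefined")

  expect_equal(chain_attenuation(c(0.14, 0.08, 0.24)), 0.398688)
  expect_equal(chain_attenuation(c(0, 0, 0)), 0)
  expect_equal(chain_attenuation(1), 1)
  expect_error(chain_attenuation(1.2), "\\[0, 1\\]")
})

test_that("residuals vanish on collinear data and the fit resists an outlier", {
  t <- seq(5, by = 5, length.out = 21)
  x <- seq(0.05, 1, length.out = 21)
  collinear <- pair_coupling(make_events(t, x, norm_max = 1),
                             make_events(t, 0.2 + 0.7 * x, norm_max = 1))
  ra <- residual_analysis(collinear, use_norm = FALSE)
  expect_true(all(abs(ra$residuals$residual) < 1e-9))

  # 20 collinear points plus one gross outlier
  y <- 0.2 + 0.7 * x
  y[11] <- 5
  robust <- pair_coupling(make_events(t, x, norm_max = 1),
                          make_events(t, y, norm_max = 1))
  ra2 <- residual_analysis(robust, use_norm = FALSE)
  expect_lt(abs(ra2$fits$slope - 0.7), 1e-6)
  expect_lt(abs(ra2$fits$intercept - 0.2), 1e-6)
  inliers <- ra2$residuals$residual[-11]
  expect_true(all(abs(inliers) < 1e-6))
  expect_equal(ra2$residuals$residual[11], 5 - (0.2 + 0.7 * x[11]),
               tolerance = 1e-6)
  # independent robust oracle: least trimmed squares on the same instance
  lts <- MASS::lqs(y ~ x, method = "lts")
  expect_lt(abs(unname(coef(lts)[2]) - unname(ra2$fits$slope)), 1e-6)

  # permuting condition labels relabels but never changes the residual set
  conds <- rep(c("dark", "stim"), length.out = 21)
  r_a <- residual_analysis(robust, conditions = conds, use_norm = FALSE)
  r_b <- residual_analysis(robust, conditions = rev(conds), use_norm = FALSE)
  expect_equal(sort(r_a$residuals$residual), sort(r_b$residuals$residual))

  degenerate <- pair_coupling(make_events(t, rep(0.5, 21), norm_max = 1),
                              make_events(t, y, norm_max = 1))
  expect_error(residual_analysis(degenerate, use_norm = FALSE), "degenerate")
})

test_that("containment width is twice the lag SD", {
  expect_equal(containment_width(0.28), 0.56)
  t <- c(10, 20, 30)
  pc <- pair_coupling(make_events(t), make_events(t + c(-0.1, 0, 0.1)))
  st <- match_interval_stats(pc)
  expect_equal(st$sd, sd(c(-0.1, 0, 0.1)))
  expect_equal(st$width, 2 * st$sd)
  expect_equal(st$max_abs, 0.1)
})
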