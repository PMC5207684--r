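test_that("two-spin sampler matches the Bessel-ratio quadrature oracle", {
  # oracle: <sigma1.sigma2> = I1(J/T)/I0(J/T), by independent 1-D integration
  for (k in c(0.5, 1, 2)) {
    m <- xy_model(matrix(c(0, k, k, 0), 2), temperature = 1)
    s <- xy_sample(m, 12000, seed = 100 + round(10 * k))
    d <- s$sx[, 1] * s$sx[, 2] + s$sy[, 1] * s$sy[, 2]
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - bessel_ratio_oracle(k)), 3 * se)
  }
})

test_that("uncoupled spins give near-zero pairwise correlations", {
  pm <- planted_model(5, 1, within_coupling = 0, between_coupling = 0)
  s <- simulate_directions(pm, 8000, seed = 2)
  cors <- direction_correlations(s, min_joint = 100)
  off <- cors$C_pairwise[upper.tri(cors$C_pairwise)]
  expect_lt(max(abs(off)), 4 / sqrt(8000))
})

test_that("decoupled strongly aligned blocks: within-pair dot near 1, between near 0", {
  pm <- planted_model(4, 2, within_coupling = 20, between_coupling = 0)
  s <- simulate_directions(pm, 3000, seed = 3)
  dot <- function(i, j) mean(s$sx[, i] * s$sx[, j] + s$sy[, i] * s$sy[, j])
  expect_gt(dot(1, 2), 0.9)
  expect_gt(dot(3, 4), 0.9)
  expect_lt(abs(dot(1, 3)), 0.2)
})

test_that("sampler rejects invalid models", {
  expect_error(xy_model(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(xy_model(matrix(0, 2, 2), temperature = -1), "positive")
})

test_that("empirical correlations converge to the generating model's moments", {
  # mean absolute deviation from the long-run reference decreases with more
  # samples (10x steps)
  pm <- planted_model(6, 2, within_coupling = 0.8, between_coupling = 0.1)
  ref <- direction_correlations(simulate_directions(pm, 40000, seed = 99),
                                min_joint = 100)$C_pairwise
  mad_at <- function(n, seed) {
    C <- direction_correlations(simulate_directions(pm, n, seed = seed),
                                min_joint = min(100, n / 2))$C_pairwise
    mean(abs(C - ref)[upper.tri(C)])
  }
  devs <- c(mad_at(200, 11), mad_at(2000, 12), mad_at(20000, 13))
  expect_true(all(diff(devs) < 0))
})

test_that("seeded determinism: identical seeds give identical panels", {
  pm <- planted_model(5, 2)
  a <- simulate_directions(pm, 500, seed = 42)
  b <- simulate_directions(pm, 500, seed = 42)
  expect_identical(a, b)
  c <- simulate_directions(pm, 500, seed = 43)
  expect_false(identical(a$sx, c$sx))
})

test_that("directions_to_gaze integrates and round-trips directions", {
  # constant direction (1,0): x strictly increasing until the border
  n <- 50
  d <- direction_panel(matrix(1, n, 1), matrix(0, n, 1))
  cfg <- synthetic_config(n_subjects = 1, speed_px = 10, speed_jitter = 0)
  g <- directions_to_gaze(d, cfg, seed = 1)
  expect_true(all(diff(g$x[, 1]) > 0))
  expect_true(all(abs(diff(g$y[, 1])) < 1e-12))

  # round trip: smooth direction series -> integrate -> extract; the
  # central-difference extractor mixes two consecutive steps, so agreement
  # is checked on a slowly turning series away from reflections
  set.seed(7)
  n_t <- 1500
  theta <- sapply(1:4, function(i) {
    cumsum(c(stats::runif(1, 0, 2 * pi), stats::rnorm(n_t - 1, 0, 0.05)))
  })
  dirs <- direction_panel(cos(theta), sin(theta))
  cfg <- synthetic_config(n_subjects = 4, speed_px = 8, speed_jitter = 0.1)
  g <- directions_to_gaze(dirs, cfg, seed = 8)
  back <- to_directions(g)
  refl <- rowSums(attr(g, "reflected")) > 0
  agree <- c()
  for (i in 1:4) {
    # back row r spans gaze rows r..r+2, i.e. direction samples r and r+1
    rows <- seq_len(nrow(back$sx))
    ok <- back$valid[, i] & !refl[rows] & !refl[rows + 1] & !refl[rows + 2]
    agree <- c(agree, mean(back$sx[ok, i] * dirs$sx[rows, i][ok] +
                             back$sy[ok, i] * dirs$sy[rows, i][ok]))
  }
  expect_gt(mean(agree), 0.95)

  expect_error(directions_to_gaze(direction_panel(matrix(1, 0, 1),
                                                  matrix(0, 0, 1)), cfg),
               "empty")
})

test_that("inject_dropout hits the target missing fraction with bursts", {
  pm <- planted_model(3, 1, within_coupling = 0.3)
  dirs <- simulate_directions(pm, 4000, seed = 1)
  g <- directions_to_gaze(dirs, synthetic_config(n_subjects = 3), seed = 2)

  expect_identical(inject_dropout(g, 0, seed = 1), g)
  expect_true(all(inject_dropout(g, 1, seed = 1)$missing))
  g3 <- inject_dropout(g, 0.3, seed = 3)
  expect_lt(abs(mean(g3$missing) - 0.3), 0.05)
  # bursts: missing runs should be much longer than i.i.d. runs
  runs <- rle(g3$missing[, 1])
  expect_gt(mean(runs$lengths[runs$values]), 3)
  expect_error(inject_dropout(g, 1.2), "rate")
})

test_that("simulate_ratings respects group structure, noise and clipping", {
  cfg0 <- synthetic_config(n_subjects = 10, rating_group_means = 7,
                           rating_noise_sd = 0)
  r0 <- simulate_ratings(cfg0, seed = 1)
  expect_true(all(r0$rating == 7))
  expect_equal(homophily(r0$rating), 1)

  # bimodal split at the scale extremes approaches homophily 1/2
  cfgb <- synthetic_config(n_subjects = 1000, rating_group_means = c(10, 0),
                           rating_noise_sd = 0)
  rb <- simulate_ratings(cfgb, seed = 1)
  expect_equal(homophily(rb$rating), (1000 - 2) / (2 * 999))

  cfgn <- synthetic_config(n_subjects = 200, rating_group_means = c(9, 1),
                           rating_noise_sd = 2)
  rn <- simulate_ratings(cfgn, seed = 5)
  expect_true(all(rn$rating >= 0 & rn$rating <= 10))
})
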