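test_that("triangular filter preserves constants and is zero-phase", {
  n <- 500
  tt <- (seq_len(n) - 1) * 4
  const <- gaze_panel(tt, matrix(123, n, 1), matrix(-7, n, 1))
  f <- lowpass_triangular(const)
  expect_equal(f$x[, 1], rep(123, n), tolerance = 1e-12)
  expect_equal(f$y[, 1], rep(-7, n), tolerance = 1e-12)

  # unit impulse -> triangular bump centred at the impulse
  imp <- matrix(0, n, 1); imp[250, 1] <- 1
  fi <- lowpass_triangular(gaze_panel(tt, imp, imp))
  expect_equal(which.max(fi$x[, 1]), 250)
  bump <- fi$x[240:260, 1]
  expect_equal(bump, rev(bump), tolerance = 1e-12)   # symmetric
  expect_equal(sum(fi$x[, 1]), 1, tolerance = 1e-9)  # unit mass

  # zero phase on a noisy sinusoid: cross-correlation peak at lag 0
  set.seed(1)
  sig <- sin(2 * pi * (1:n) / 50) + rnorm(n, sd = 0.3)
  fs <- lowpass_triangular(gaze_panel(tt, cbind(sig), cbind(sig)))
  cc <- ccf(sig, fs$x[, 1], lag.max = 15, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filter expands the missing mask by half a window each side", {
  n <- 200
  tt <- (seq_len(n) - 1) * 4   # 250 Hz
  x <- matrix(seq_len(n), n, 1)
  x[100, 1] <- NA
  f <- lowpass_triangular(gaze_panel(tt, x, x), window_ms = 80)
  # 40 ms at 250 Hz = 10 samples each side -> 21 missing
  expect_equal(sum(f$missing), 21)
  expect_equal(which(f$missing[, 1]), 90:110)
  expect_error(lowpass_triangular(gaze_panel(tt, x, x), window_ms = 1),
               "window")
})

test_that("subject exclusion uses a strict missing-fraction threshold", {
  n <- 100
  tt <- (seq_len(n) - 1) * 4
  x <- matrix(rnorm(3 * n), n, 3)
  x[1:21, 2] <- NA          # 21% missing
  p <- gaze_panel(tt, x, x)
  kept <- exclude_subjects(p, 0.2)
  expect_equal(kept$subjects, c("s1", "s3"))
  expect_equal(attr(kept, "excluded"), "s2")

  # threshold 0 with any missing sample -> removed (strict inequality)
  x2 <- matrix(rnorm(2 * n), n, 2)
  x2[5, 1] <- NA
  p2 <- gaze_panel(tt, x2, x2)
  expect_equal(exclude_subjects(p2, 0)$subjects, "s2")
  expect_error(exclude_subjects(gaze_panel(tt, x2 * NA, x2 * NA)),
               "unusable")
})

test_that("low-rank interpolation reconstructs gaps on shared-component data", {
  # rank-1 panel: every subject a scaled copy of one latent trajectory
  set.seed(2)
  n <- 400
  latent <- cumsum(rnorm(n))
  w <- runif(6, 0.5, 2)
  x <- outer(latent, w) + matrix(rnorm(n * 6, sd = 0.05), n, 6)
  truth <- x[150:200, 3]
  x[150:200, 3] <- NA
  tt <- (seq_len(n) - 1) * 4
  p <- gaze_panel(tt, x, x)
  out <- interpolate_outliers(p, rank = 1, flag_outliers = FALSE)
  expect_gt(cor(attr(out, "filled_mask")[, 3][150:200] * 0 + out$x[150:200, 3],
                truth), 0.9)
  # observed samples untouched
  obs <- !p$missing
  expect_equal(out$x[obs], p$x[obs])
  # original mask retained for correlation bookkeeping
  expect_equal(out$missing, p$missing)

  # no missing data -> identity
  clean <- outer(latent, w[1:3])
  p0 <- gaze_panel(tt, clean + 1, clean)
  expect_equal(interpolate_outliers(p0, rank = 1,
                                    flag_outliers = FALSE)$x, p0$x)
  expect_error(interpolate_outliers(p, rank = 6), "rank")
  xall <- x; xall[, 2] <- NA
  expect_error(interpolate_outliers(gaze_panel(tt, xall, xall), rank = 1),
               "entirely-missing")
})

test_that("segmentation drops remainders and conserves samples", {
  rate <- 250
  make <- function(secs) {
    n <- secs * rate
    tt <- (seq_len(n) - 1) * 1000 / rate
    gaze_panel(tt, matrix(rnorm(2 * n), n, 2), matrix(rnorm(2 * n), n, 2))
  }
  expect_length(segment_panel(make(60), 30), 2)
  expect_length(segment_panel(make(45), 30), 1)
  s30 <- segment_panel(make(30), 30)
  expect_length(s30, 1)
  expect_equal(nrow(s30[[1]]$x), 30 * rate)
  expect_error(segment_panel(make(10), 30), "unusable")
  # segment sample counts sum to the retained total
  segs <- segment_panel(make(95), 30)
  expect_equal(sum(vapply(segs, function(s) nrow(s$x), numeric(1))),
               3 * 30 * rate)
})

test_that("direction extraction follows central differences and flags fixations", {
  tt <- c(0, 4, 8)
  p <- gaze_panel(tt, cbind(c(0, 1, 2)), cbind(c(0, 0, 0)))
  d <- to_directions(p)
  expect_equal(c(d$sx[1, 1], d$sy[1, 1]), c(1, 0))

  p45 <- gaze_panel(tt, cbind(c(0, 1, 2)), cbind(c(0, 1, 2)))
  d45 <- to_directions(p45)
  expect_equal(c(d45$sx[1, 1], d45$sy[1, 1]), c(sqrt(2) / 2, sqrt(2) / 2))

  fix <- gaze_panel(tt, cbind(c(5, 5, 5)), cbind(c(3, 3, 3)))
  expect_false(to_directions(fix)$valid[1, 1])
})

test_that("direction extraction is translation- and scale-invariant", {
  p <- make_line_panel(n_t = 100, angles = c(0.3, 2.1), noise_sd = 1)
  d0 <- to_directions(p)
  shifted <- gaze_panel(p$times, p$x + 500, p$y - 200)
  scaled <- gaze_panel(p$times, p$x * 3.7, p$y * 3.7)
  expect_equal(to_directions(shifted)$sx, d0$sx, tolerance = 1e-9)
  expect_equal(to_directions(scaled)$sx, d0$sx, tolerance = 1e-9)
  expect_equal(to_directions(scaled)$sy, d0$sy, tolerance = 1e-9)
})

test_that("gaze CSV round-trips through the pipeline dialect", {
  p <- make_line_panel(n_t = 50, angles = c(0, 1, 2), noise_sd = 2)
  p$x[10, 2] <- NA; p$missing[10, 2] <- TRUE
  path <- tempfile(fileext = ".csv")
  write_gaze_csv(p, path)
  q <- read_gaze_csv(path)
  expect_equal(q$x, p$x)
  expect_equal(q$missing, p$missing)
  expect_equal(q$subjects, p$subjects)
  unlink(path)
})
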