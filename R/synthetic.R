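#' Planted XY model with community structure
#'
#' Builds the ground-truth generating model for synthetic gaze experiments:
#' viewers are split into groups, with alignment coupling `within_coupling`
#' inside a group and `between_coupling` across groups. This is the forward
#' model whose Boltzmann samples the inference pipeline is expected to
#' recover.
#'
#' @param n_subjects number of viewers (study default 25).
#' @param n_groups number of planted communities.
#' @param within_coupling,between_coupling coupling values (dimensionless).
#' @param h optional N x 2 field matrix (default zero: no net gaze drift).
#' @param temperature operating temperature (default 1).
#' @return list of class `planted_model` with the underlying [xy_model] and
#'   the per-viewer `group` labels.
#' @export
planted_model <- function(n_subjects = 25, n_groups = 2,
                          within_coupling = 0.5, between_coupling = 0.05,
                          h = NULL, temperature = 1) {
  groups <- sort(rep_len(seq_len(n_groups), n_subjects))
  J <- matrix(between_coupling, n_subjects, n_subjects)
  same <- outer(groups, groups, `==`)
  J[same] <- within_coupling
  diag(J) <- 0
  structure(
    list(model = xy_model(J, h, temperature), group = groups),
    class = "planted_model"
  )
}

#' Synthetic experiment configuration
#'
#' Defaults mirror the study's recording setup: 25 viewers, 30-second
#' segments sampled at 250 Hz on a 1440 x 2560 pixel screen, ratings on a
#' 0-10 scale.
#'
#' @param n_subjects,segment_seconds,sample_rate_hz,screen_px recording
#'   geometry; `screen_px` is `c(height, width)` in pixels.
#' @param n_groups,within_coupling,between_coupling planted structure.
#' @param dropout_rate fraction of samples lost to tracker lapses, in
#'   \[0, 1\].
#' @param rating_group_means per-group mean preference rating (0-10).
#' @param rating_noise_sd rater noise standard deviation.
#' @param speed_px,speed_jitter gaze speed (pixels per sample) and its
#'   multiplicative jitter; a generator choice, the analysis only uses
#'   directions.
#' @param mc_thin Metropolis sweeps between stored direction samples
#'   (default 10, giving approximately independent draws; lower values give
#'   temporally autocorrelated series at the cost of much noisier
#'   finite-window correlation estimates).
#' @param rng_seed default seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 25, segment_seconds = 30,
                             sample_rate_hz = 250,
                             screen_px = c(1440, 2560),
                             n_groups = 2, within_coupling = 0.5,
                             between_coupling = 0.05, dropout_rate = 0.02,
                             rating_group_means = c(7, 4),
                             rating_noise_sd = 1.5,
                             speed_px = 30, speed_jitter = 0.2,
                             mc_thin = 10L, rng_seed = 1L) {
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate must be in [0, 1]")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  if (any(rating_group_means < 0 | rating_group_means > 10))
    stop("rating group means must lie in [0, 10]")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate direction series from a planted model
#'
#' Forward model of the analysis: draws `n_samples` thinned, equilibrated
#' configurations of N unit direction vectors from the Boltzmann
#' distribution of the planted XY model at its temperature.
#'
#' @param planted a [planted_model] (or bare [xy_model]).
#' @param n_samples retained Monte Carlo samples.
#' @param seed integer seed.
#' @param thin_sweeps sweeps between retained samples.
#' @return [direction_panel].
#' @export
simulate_directions <- function(planted, n_samples, seed, thin_sweeps = 10L) {
  model <- if (inherits(planted, "planted_model")) planted$model else planted
  xy_sample(model, n_samples, seed, thin_sweeps = thin_sweeps)
}

#' Integrate directions into on-screen gaze trajectories
#'
#' Converts unit direction vectors into pixel coordinates by integrating
#' with a positive speed profile (constant speed with small multiplicative
#' jitter) and reflecting at the screen borders. The direction of travel at
#' non-reflected samples is recoverable by the preprocessing direction
#' extractor.
#'
#' @param dirs a [direction_panel].
#' @param config a [synthetic_config] (screen size, speed, sampling rate).
#' @param seed seed for the speed jitter.
#' @return [gaze_panel]; the attribute `reflected` marks samples at which a
#'   border reflection occurred.
#' @export
directions_to_gaze <- function(dirs, config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(dirs, "direction_panel"))
  n_t <- nrow(dirs$sx); n_s <- ncol(dirs$sx)
  if (n_t == 0 || n_s == 0) stop("empty direction panel")
  if (any(!is.finite(dirs$sx[dirs$valid])) || any(!is.finite(dirs$sy[dirs$valid])))
    stop("directions must be finite")
  hgt <- config$screen_px[1]; wid <- config$screen_px[2]
  set.seed(seed %% 2^31)
  x <- matrix(0, n_t + 1, n_s); y <- matrix(0, n_t + 1, n_s)
  reflected <- matrix(FALSE, n_t + 1, n_s)
  for (i in seq_len(n_s)) {
    speed <- config$speed_px *
      pmax(0.05, 1 + config$speed_jitter * stats::rnorm(n_t))
    px <- wid / 2; py <- hgt / 2
    x[1, i] <- px; y[1, i] <- py
    for (t in seq_len(n_t)) {
      dx <- if (dirs$valid[t, i]) dirs$sx[t, i] else 0
      dy <- if (dirs$valid[t, i]) dirs$sy[t, i] else 0
      px <- px + speed[t] * dx
      py <- py + speed[t] * dy
      # reflect at borders (possibly repeatedly for large steps)
      while (px < 0 || px > wid) {
        px <- if (px < 0) -px else 2 * wid - px
        reflected[t + 1, i] <- TRUE
      }
      while (py < 0 || py > hgt) {
        py <- if (py < 0) -py else 2 * hgt - py
        reflected[t + 1, i] <- TRUE
      }
      x[t + 1, i] <- px; y[t + 1, i] <- py
    }
  }
  dt_ms <- 1000 / config$sample_rate_hz
  out <- gaze_panel(times = dt_ms * (seq_len(n_t + 1) - 1), x = x, y = y,
                    subjects = dirs$subjects,
                    sample_rate_hz = config$sample_rate_hz)
  attr(out, "reflected") <- reflected
  out
}

#' Inject burst-structured missing data
#'
#' Marks contiguous episodes of samples as missing, per subject, emulating
#' brief tracker lapses. Episode lengths are geometric (mean
#' `mean_burst`) and onsets are placed so the expected missing fraction
#' equals `rate`. Bursts rather than i.i.d. drops exercise the +/-40 ms mask
#' expansion of the low-pass filter.
#'
#' @param panel a [gaze_panel].
#' @param rate target missing fraction in \[0, 1\].
#' @param seed integer seed.
#' @param mean_burst mean burst length in samples (default 25 = 100 ms at
#'   250 Hz).
#' @return the panel with an updated missing mask (`NA` positions).
#' @export
inject_dropout <- function(panel, rate, seed = 1L, mean_burst = 25) {
  stopifnot(inherits(panel, "gaze_panel"))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (rate == 0) return(panel)
  n_t <- nrow(panel$x); n_s <- ncol(panel$x)
  set.seed(seed %% 2^31)
  miss <- panel$missing
  if (rate == 1) {
    miss[] <- TRUE
  } else {
    p_start <- rate / (mean_burst * (1 - rate))  # burst onset hazard
    for (i in seq_len(n_s)) {
      t <- 1L
      while (t <= n_t) {
        if (stats::runif(1) < p_start) {
          len <- 1L + stats::rgeom(1, 1 / mean_burst)
          miss[t:min(n_t, t + len - 1L), i] <- TRUE
          t <- t + len
        }
        t <- t + 1L
      }
    }
  }
  panel$missing <- miss
  panel$x[miss] <- NA_real_
  panel$y[miss] <- NA_real_
  panel
}

#' Simulate preference ratings with planted homophily
#'
#' Each viewer's rating is their group mean plus Gaussian noise, clipped to
#' the \[0, 10\] scale (clipping, not resampling, at the boundaries).
#'
#' @param config a [synthetic_config]; `rating_group_means` and
#'   `rating_noise_sd` control agreement structure.
#' @param seed integer seed.
#' @param group optional per-subject group labels (defaults to the same
#'   balanced split as [planted_model]).
#' @return data.frame with columns `subject`, `rating`, `group`.
#' @export
simulate_ratings <- function(config = synthetic_config(), seed = 1L,
                             group = NULL) {
  n <- config$n_subjects
  if (is.null(group))
    group <- sort(rep_len(seq_along(config$rating_group_means), n))
  means <- config$rating_group_means[group]
  set.seed(seed %% 2^31)
  r <- means + config$rating_noise_sd * stats::rnorm(n)
  r <- pmin(10, pmax(0, r))
  data.frame(subject = paste0("s", seq_len(n)), rating = r, group = group,
             stringsAsFactors = FALSE)
}

#' Generate one complete synthetic "video"
#'
#' Convenience wrapper: planted model -> Boltzmann direction series ->
#' integrated gaze trajectories -> burst dropout, plus ratings.
#'
#' @param config a [synthetic_config].
#' @param seed integer seed.
#' @param duration_s duration; defaults to `segment_seconds`.
#' @return list with `panel` ([gaze_panel]), `ratings`, `planted`
#'   (the [planted_model]) and `directions` (the true direction series).
#' @export
simulate_video <- function(config = synthetic_config(), seed = 1L,
                           duration_s = config$segment_seconds) {
  pm <- planted_model(config$n_subjects, config$n_groups,
                      config$within_coupling, config$between_coupling)
  n_samp <- as.integer(duration_s * config$sample_rate_hz)
  dirs <- simulate_directions(pm, n_samp, seed = seed,
                              thin_sweeps = config$mc_thin)
  panel <- directions_to_gaze(dirs, config, seed = seed + 1L)
  panel <- inject_dropout(panel, config$dropout_rate, seed = seed + 2L)
  ratings <- simulate_ratings(config, seed = seed + 3L, group = pm$group)
  list(panel = panel, ratings = ratings, planted = pm, directions = dirs)
}
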