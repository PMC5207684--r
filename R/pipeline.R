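#' Analysis run configuration
#'
#' Bundles every tunable parameter of the per-video pipeline with its study
#' default: 80 ms filter window, 20\% missing-data exclusion, 30 s segments,
#' the 0.17-1.43 temperature grid, the 0.99 fit fidelity target, and the
#' criticality floor (`tc_floor = 0.82`) used to subset videos for the
#' modularity correlation.
#'
#' @param window_ms low-pass window (ms).
#' @param max_missing exclusion threshold on missing fraction.
#' @param segment_s segment length (s).
#' @param interp_rank low-rank interpolation rank (0 disables the step).
#' @param min_joint minimum jointly valid samples per pair.
#' @param fidelity,max_iter,fit_samples Boltzmann-learning controls.
#' @param t_min,t_max,t_points temperature grid.
#' @param scan_samples Monte Carlo samples per grid temperature.
#' @param tc_floor criticality floor for the `T_c`-vs-`Q` pairing.
#' @param seed base seed; every stage derives its own stream from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(window_ms = 80, max_missing = 0.2, segment_s = 30,
                       interp_rank = 1, min_joint = 100,
                       fidelity = 0.99, max_iter = 500L,
                       fit_samples = 2000L, t_min = 0.17, t_max = 1.43,
                       t_points = 22L, scan_samples = 3000L,
                       tc_floor = 0.82, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis on one video
#'
#' Executes the whole chain per 30-s segment — low-pass filter, subject
#' exclusion, low-rank gap interpolation, direction extraction, pairwise
#' correlations, maximum-entropy fit, temperature scan, network/modularity —
#' then averages couplings and critical temperatures over segments and
#' joins the rating homophily.
#'
#' @param panel a [gaze_panel] (or path to a gaze CSV).
#' @param ratings optional numeric vector of this video's per-subject
#'   ratings (for homophily).
#' @param config a [run_config].
#' @param video id string for the summary row.
#' @return list of class `video_summary`: a one-row `summary` data.frame
#'   (video, n_subjects_retained, n_segments, C_x, C_y, C_sigma, J_avg,
#'   T_c, T_c_eigen, J_o, Q, n_communities, homophily, rating_mean), the
#'   per-segment objects, and a `log` of exclusions/convergence events.
#'   Unusable videos (shorter than one segment, or all subjects excluded)
#'   return a `skipped` record instead of failing.
#' @export
run_video <- function(panel, ratings = NULL, config = run_config(),
                      video = "video") {
  if (is.character(panel)) panel <- read_gaze_csv(panel)
  stopifnot(inherits(panel, "gaze_panel"))
  log <- character(0)

  segs <- tryCatch(segment_panel(panel, config$segment_s),
                   error = function(e) e)
  if (inherits(segs, "error")) {
    return(structure(list(summary = NULL, skipped = TRUE,
                          reason = conditionMessage(segs), video = video),
                     class = "video_summary"))
  }

  seg_results <- list()
  for (k in seq_along(segs)) {
    res <- tryCatch(
      analyse_segment(segs[[k]], config, seed = config$seed + 1000L * k),
      error = function(e) e)
    if (inherits(res, "error")) {
      log <- c(log, sprintf("segment %d failed: %s", k, conditionMessage(res)))
      next
    }
    log <- c(log, res$log)
    seg_results[[length(seg_results) + 1L]] <- res
  }
  if (length(seg_results) == 0) {
    return(structure(list(summary = NULL, skipped = TRUE,
                          reason = paste(log, collapse = "; "), video = video),
                     class = "video_summary"))
  }

  models <- lapply(seg_results, function(r) r$fit$model)
  scans <- lapply(seg_results, function(r) r$scan)
  avg <- average_over_segments(models, scans)
  J_avg <- mean(avg$J[upper.tri(avg$J)])
  tc_eig <- mean(vapply(models, tc_from_eigenvalue, numeric(1)))
  net <- tryCatch(suppressWarnings(
    viewer_network(avg$J, seed = config$seed + 7L)),
    error = function(e) NULL)

  cx <- mean(vapply(seg_results, function(r) r$isc[["C_x"]], numeric(1)))
  cy <- mean(vapply(seg_results, function(r) r$isc[["C_y"]], numeric(1)))
  cs <- mean(vapply(seg_results, function(r) r$cors$C_sigma, numeric(1)))

  hom <- NA_real_
  rmean <- NA_real_
  if (!is.null(ratings) && length(ratings) >= 2) {
    hom <- homophily(ratings)
    rmean <- mean(ratings)
  }

  summary <- data.frame(
    video = video,
    n_subjects_retained = length(avg$subjects),
    n_segments = length(seg_results),
    C_x = cx, C_y = cy, C_sigma = cs, J_avg = J_avg,
    T_c = avg$T_c, T_c_eigen = tc_eig,
    J_o = if (!is.null(net)) net$J_o else NA_real_,
    Q = if (!is.null(net)) net$Q else NA_real_,
    n_communities = if (!is.null(net)) length(unique(net$communities))
                    else NA_integer_,
    homophily = hom, rating_mean = rmean,
    stringsAsFactors = FALSE
  )
  structure(list(summary = summary, segments = seg_results, network = net,
                 J = avg$J, skipped = FALSE, log = log, video = video),
            class = "video_summary")
}

# one 30-s increment: preprocess -> directions -> correlations -> fit ->
# thermo scan
analyse_segment <- function(seg, config, seed) {
  log <- character(0)
  filt <- lowpass_triangular(seg, config$window_ms)
  kept <- exclude_subjects(filt, config$max_missing)
  exc <- attr(kept, "excluded")
  if (length(exc)) log <- c(log, paste("excluded:", paste(exc, collapse = ",")))
  if (config$interp_rank > 0 && ncol(kept$x) > config$interp_rank &&
      any(kept$missing)) {
    kept <- interpolate_outliers(kept, rank = config$interp_rank)
  }
  isc <- position_isc(kept)
  dirs <- to_directions(kept)
  cors <- direction_correlations(dirs, min_joint = config$min_joint)
  fit <- fit_xy(cors$C_pairwise, cors$mu, seed = seed,
                n_samples = config$fit_samples,
                max_iter = config$max_iter,
                fidelity_target = config$fidelity)
  if (!fit$report$converged)
    log <- c(log, sprintf("fit not converged (fidelity %.3f after %d iter)",
                          fit$report$fidelity, fit$report$iterations))
  scan <- scan_temperatures(fit$model, t_min = config$t_min,
                            t_max = config$t_max, n_points = config$t_points,
                            n_samples = config$scan_samples,
                            seed = seed + 500L)
  list(isc = isc, cors = cors, dirs = dirs, fit = fit, scan = scan, log = log)
}

#' Run a study across videos and report the headline correlations
#'
#' Runs [run_video] on every entry of the manifest, assembles the per-video
#' summary table, and computes Pearson r / p for each reported pairing:
#' homophily vs population rating, position and direction ISC vs population
#' rating, T_c vs C_sigma, T_c vs Q on the subset above the criticality
#' floor, and T_c vs population rating. Each pairing uses the maximal set
#' of videos with both quantities available.
#'
#' @param videos named list; each element is a list with `panel` (a
#'   [gaze_panel] or gaze CSV path) and optional `ratings` (numeric vector).
#' @param population optional data.frame `video,population_rating`.
#' @param config a [run_config].
#' @return list of class `study_result`: `summary` (per-video data.frame,
#'   skipped videos excluded), `skipped`, `correlations` (one row per
#'   pairing with r, p, n), `runs` (full per-video objects).
#' @export
run_study <- function(videos, population = NULL, config = run_config()) {
  if (is.null(names(videos)) || any(!nzchar(names(videos))))
    names(videos) <- paste0("video", seq_along(videos))
  runs <- list(); skipped <- list()
  for (v in names(videos)) {
    cfg <- config
    cfg$seed <- config$seed + match(v, names(videos)) * 100000L
    r <- run_video(videos[[v]]$panel, videos[[v]]$ratings, cfg, video = v)
    if (isTRUE(r$skipped)) skipped[[v]] <- r$reason else runs[[v]] <- r
  }
  if (length(runs) == 0) stop("no usable videos in the manifest")
  summary <- do.call(rbind, lapply(runs, `[[`, "summary"))
  rownames(summary) <- NULL
  if (!is.null(population)) {
    summary$population_rating <-
      population$population_rating[match(summary$video, population$video)]
  } else {
    summary$population_rating <- NA_real_
  }

  correlations <- NULL
  if (nrow(summary) >= 3) {
    pairings <- list(
      c("homophily", "population_rating"),
      c("C_x", "population_rating"),
      c("C_y", "population_rating"),
      c("C_sigma", "population_rating"),
      c("T_c", "C_sigma"),
      c("T_c", "population_rating"),
      c("T_c_eigen", "T_c")
    )
    rows <- lapply(pairings, function(p) {
      res <- tryCatch(pearson_with_p(summary[[p[1]]], summary[[p[2]]]),
                      error = function(e) NULL)
      data.frame(x = p[1], y = p[2],
                 r = if (is.null(res)) NA_real_ else res$r,
                 p = if (is.null(res)) NA_real_ else res$p,
                 n = if (is.null(res)) 0L else res$n,
                 stringsAsFactors = FALSE)
    })
    # T_c vs Q restricted to near-critical videos
    crit <- summary[!is.na(summary$T_c) & summary$T_c > config$tc_floor, ]
    rows[[length(rows) + 1L]] <- local({
      res <- tryCatch(pearson_with_p(crit$T_c, crit$Q),
                      error = function(e) NULL)
      data.frame(x = sprintf("T_c (> %.2f)", config$tc_floor), y = "Q",
                 r = if (is.null(res)) NA_real_ else res$r,
                 p = if (is.null(res)) NA_real_ else res$p,
                 n = if (is.null(res)) 0L else res$n,
                 stringsAsFactors = FALSE)
    })
    correlations <- do.call(rbind, rows)
  }
  structure(list(summary = summary, skipped = skipped,
                 correlations = correlations, runs = runs),
            class = "study_result")
}

#' Write the per-video summary table as TSV
#' @param study a `study_result` (or the summary data.frame itself).
#' @param path output path.
#' @export
write_summary_tsv <- function(study, path) {
  df <- if (inherits(study, "study_result")) study$summary else study
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
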