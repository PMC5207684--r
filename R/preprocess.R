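#' Zero-phase triangular low-pass filter
#'
#' Smooths each viewer's gaze coordinates with a symmetric triangular window
#' of total width `window_ms` (80 ms by default; 21 taps at 250 Hz),
#' normalised to unit sum so constant signals pass unchanged. Because the
#' filter mixes neighbouring samples, every sample within half a window of a
#' missing sample is itself marked missing (+/-40 ms at the default), which
#' matches the implicit mask expansion of the zero-phase filtering step.
#' Near the panel edges the kernel is renormalised over available taps.
#'
#' @param panel a [gaze_panel].
#' @param window_ms total filter width in milliseconds (> 0).
#' @return filtered [gaze_panel] with the expanded missing mask.
#' @export
lowpass_triangular <- function(panel, window_ms = 80) {
  stopifnot(inherits(panel, "gaze_panel"))
  if (window_ms <= 0) stop("window_ms must be positive")
  len <- round(window_ms / 1000 * panel$sample_rate_hz)
  if (len < 2) stop("window shorter than 2 samples at this sampling rate")
  half <- floor(len / 2)
  w <- (half + 1) - abs(seq(-half, half))       # symmetric triangle, odd taps
  n_t <- nrow(panel$x)

  smooth_col <- function(v, miss) {
    v0 <- ifelse(miss, 0, v)
    ok <- as.numeric(!miss)
    num <- stats::filter(v0, w, sides = 2)
    den <- stats::filter(ok, w, sides = 2)
    # stats::filter returns NA at the edges; recompute there over the
    # in-range taps (renormalised kernel)
    edge <- which(is.na(num))
    for (t in edge) {
      idx <- max(1, t - half):min(n_t, t + half)
      kw <- w[idx - t + half + 1]
      num[t] <- sum(kw * v0[idx])
      den[t] <- sum(kw * ok[idx])
    }
    ifelse(den > 0, as.numeric(num) / as.numeric(den), NA_real_)
  }

  # expand mask by half a window on each side
  expand <- function(miss) {
    out <- miss
    idx <- which(miss)
    for (t in idx) out[max(1, t - half):min(n_t, t + half)] <- TRUE
    out
  }

  x <- panel$x; y <- panel$y; miss <- panel$missing
  for (i in seq_len(ncol(x))) {
    mi <- miss[, i]
    x[, i] <- smooth_col(panel$x[, i], mi)
    y[, i] <- smooth_col(panel$y[, i], mi)
    miss[, i] <- expand(mi)
  }
  x[miss] <- NA_real_
  y[miss] <- NA_real_
  gaze_panel(panel$times, x, y, missing = miss, subjects = panel$subjects,
             sample_rate_hz = panel$sample_rate_hz)
}

#' Exclude viewers with excessive missing data
#'
#' Viewers whose missing fraction for this video strictly exceeds
#' `max_missing_fraction` (20\% by default) are removed from the panel.
#'
#' @param panel a [gaze_panel].
#' @param max_missing_fraction exclusion threshold.
#' @return pruned [gaze_panel]; excluded ids in attribute `excluded`.
#' @export
exclude_subjects <- function(panel, max_missing_fraction = 0.2) {
  stopifnot(inherits(panel, "gaze_panel"))
  frac <- colMeans(panel$missing)
  drop <- frac > max_missing_fraction
  if (all(drop)) stop("all subjects excluded: video unusable")
  out <- gaze_panel(panel$times, panel$x[, !drop, drop = FALSE],
                    panel$y[, !drop, drop = FALSE],
                    missing = panel$missing[, !drop, drop = FALSE],
                    subjects = panel$subjects[!drop],
                    sample_rate_hz = panel$sample_rate_hz)
  attr(out, "excluded") <- panel$subjects[drop]
  out
}

# Internal: per-subject outlier flagging by the MAD rule (5 MADs from the
# running median of each coordinate). The study names pupil-occlusion
# artifacts but no criterion; a robust scale rule is the standard choice.
flag_outliers <- function(panel, n_mads = 5) {
  out <- matrix(FALSE, nrow(panel$x), ncol(panel$x))
  for (i in seq_len(ncol(panel$x))) {
    for (coord in list(panel$x[, i], panel$y[, i])) {
      ok <- !is.na(coord)
      if (sum(ok) < 10) next
      med <- stats::median(coord[ok])
      madv <- stats::mad(coord[ok])
      if (madv > 0) out[, i] <- out[, i] | (!is.na(coord) & abs(coord - med) > n_mads * madv)
    }
  }
  out
}

#' Fill missing and outlier samples by low-rank cross-viewer reconstruction
#'
#' Replaces missing (and, optionally, MAD-flagged outlier) samples of each
#' coordinate with a truncated-SVD reconstruction across viewers, iterated
#' EM-style until the imputed entries stabilise. This effectively inserts an
#' interpolation from the other viewers for the gaps, standing in for the
#' sparse-PCA step of the original pipeline. Observed samples are never
#' altered, and the original missing mask is retained so that correlation
#' estimates can keep excluding those samples.
#'
#' @param panel a [gaze_panel] with at least 2 viewers.
#' @param rank reconstruction rank (must be < number of viewers).
#' @param flag_outliers also impute MAD-rule outliers (default TRUE).
#' @param max_iter,tol EM iteration controls.
#' @return [gaze_panel] with gaps filled; the original mask is kept in the
#'   `missing` field for downstream bookkeeping.
#' @export
interpolate_outliers <- function(panel, rank = 1, flag_outliers = TRUE,
                                 max_iter = 50, tol = 1e-6) {
  stopifnot(inherits(panel, "gaze_panel"))
  n_s <- ncol(panel$x)
  if (n_s < 2) stop("need at least 2 retained subjects")
  if (rank >= n_s) stop("rank must be smaller than the number of subjects")
  fill <- panel$missing
  if (flag_outliers) fill <- fill | flag_outliers(panel)
  if (any(colMeans(fill) == 1)) stop("entirely-missing subject: exclude first")

  impute <- function(M, fill) {
    # start gaps from column means of observed samples
    for (i in seq_len(ncol(M))) {
      mi <- fill[, i]
      if (any(mi)) M[mi, i] <- mean(M[!mi, i])
    }
    prev <- M[fill]
    for (k in seq_len(max_iter)) {
      sv <- svd(M, nu = rank, nv = rank)
      recon <- sv$u %*% (diag(sv$d[seq_len(rank)], rank) %*% t(sv$v))
      M[fill] <- recon[fill]
      delta <- sqrt(mean((M[fill] - prev)^2))
      prev <- M[fill]
      if (is.nan(delta) || delta < tol) break
    }
    M
  }

  x <- panel$x; y <- panel$y
  x[fill] <- NA_real_; y[fill] <- NA_real_
  xf <- impute(x, fill)
  yf <- impute(y, fill)
  out <- gaze_panel(panel$times, xf, yf, missing = panel$missing,
                    subjects = panel$subjects,
                    sample_rate_hz = panel$sample_rate_hz)
  attr(out, "filled_mask") <- fill
  out
}

#' Split a panel into consecutive fixed-length segments
#'
#' Analysis runs on non-overlapping increments (30 s by default); a trailing
#' remainder shorter than one segment is dropped, and panels shorter than a
#' single segment are rejected as unusable.
#'
#' @param panel a [gaze_panel].
#' @param seconds segment duration.
#' @return list of [gaze_panel] segments (half-open sample windows).
#' @export
segment_panel <- function(panel, seconds = 30) {
  stopifnot(inherits(panel, "gaze_panel"))
  n_per <- as.integer(round(seconds * panel$sample_rate_hz))
  n_t <- nrow(panel$x)
  k <- n_t %/% n_per
  if (k < 1) stop("panel shorter than one segment: video unusable")
  lapply(seq_len(k), function(s) {
    idx <- ((s - 1L) * n_per + 1L):(s * n_per)
    gaze_panel(panel$times[idx], panel$x[idx, , drop = FALSE],
               panel$y[idx, , drop = FALSE],
               missing = panel$missing[idx, , drop = FALSE],
               subjects = panel$subjects,
               sample_rate_hz = panel$sample_rate_hz)
  })
}

#' Extract unit eye-movement directions from gaze positions
#'
#' Velocity by central differences, \eqn{v_i(t) = 0.5\,(r_i(t+1) -
#' r_i(t-1))}, normalised to unit vectors \eqn{\sigma_i(t) = v_i(t)/|v_i(t)|}.
#' A sample is invalid when any sample in its 3-point stencil is missing or
#' when the speed is below `zero_tol` (fixations have no defined direction).
#'
#' @param panel a [gaze_panel] with at least 3 samples.
#' @param zero_tol speed threshold (pixels/sample) below which the direction
#'   is undefined.
#' @param use_missing_mask honour the missing mask (set `FALSE` only for
#'   panels whose gaps were filled and are meant to be used).
#' @return [direction_panel].
#' @export
to_directions <- function(panel, zero_tol = 1e-9, use_missing_mask = TRUE) {
  stopifnot(inherits(panel, "gaze_panel"))
  n_t <- nrow(panel$x); n_s <- ncol(panel$x)
  if (n_t < 3) stop("need at least 3 samples for central differences")
  idx <- 2:(n_t - 1)
  vx <- 0.5 * (panel$x[idx + 1, , drop = FALSE] - panel$x[idx - 1, , drop = FALSE])
  vy <- 0.5 * (panel$y[idx + 1, , drop = FALSE] - panel$y[idx - 1, , drop = FALSE])
  speed <- sqrt(vx^2 + vy^2)
  valid <- is.finite(speed) & speed > zero_tol
  if (use_missing_mask) {
    m <- panel$missing
    stencil_ok <- !(m[idx - 1, , drop = FALSE] | m[idx, , drop = FALSE] |
                      m[idx + 1, , drop = FALSE])
    valid <- valid & stencil_ok
  }
  sx <- matrix(NA_real_, n_t - 2, n_s); sy <- sx
  sx[valid] <- (vx / speed)[valid]
  sy[valid] <- (vy / speed)[valid]
  direction_panel(sx, sy, valid = valid, subjects = panel$subjects)
}
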