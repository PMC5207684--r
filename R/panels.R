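#' Multi-viewer gaze position panel
#'
#' Time-aligned horizontal and vertical gaze positions for all viewers of one
#' video (segment), on a uniform sampling grid, with a per-sample missing-data
#' mask. Positions are in screen pixels; times in milliseconds.
#'
#' @param times numeric vector of sample times (ms), uniform and increasing.
#' @param x,y T x N matrices of gaze coordinates (rows = samples,
#'   columns = viewers). `NA` entries are treated as missing.
#' @param missing optional T x N logical mask; defaults to `is.na(x) | is.na(y)`.
#' @param subjects viewer ids (default `s1..sN`).
#' @param sample_rate_hz sampling rate; inferred from `times` when omitted.
#' @return object of class `gaze_panel`.
#' @export
gaze_panel <- function(times, x, y, missing = NULL, subjects = NULL,
                       sample_rate_hz = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("x and y must share dimensions")
  if (length(times) != nrow(x)) stop("times must match rows of x")
  if (nrow(x) >= 2) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
      stop("times must be on a uniform grid")
    if (is.null(sample_rate_hz)) sample_rate_hz <- 1000 / stats::median(dt)
  } else if (is.null(sample_rate_hz)) {
    stop("sample_rate_hz required for panels with < 2 samples")
  }
  if (is.null(missing)) missing <- is.na(x) | is.na(y)
  missing <- missing | is.na(x) | is.na(y)
  if (!all(dim(missing) == dim(x))) stop("missing mask must match x")
  if (is.null(subjects)) subjects <- paste0("s", seq_len(ncol(x)))
  structure(
    list(times = as.numeric(times), x = unname(x), y = unname(y),
         missing = unname(missing), subjects = as.character(subjects),
         sample_rate_hz = sample_rate_hz),
    class = "gaze_panel"
  )
}

#' @export
print.gaze_panel <- function(x, ...) {
  cat(sprintf("<gaze_panel> %d viewers x %d samples @ %g Hz (%.1f s), %.1f%% missing\n",
              ncol(x$x), nrow(x$x), x$sample_rate_hz,
              nrow(x$x) / x$sample_rate_hz, 100 * mean(x$missing)))
  invisible(x)
}

#' Per-sample eye-movement direction panel
#'
#' Unit 2-vectors \eqn{\sigma_i(t)} of eye-movement direction per viewer and
#' sample, with a validity mask (a direction is undefined where velocity is
#' zero or the finite-difference stencil touches missing data).
#'
#' @param sx,sy T x N matrices of direction components.
#' @param valid T x N logical mask of defined directions.
#' @param subjects viewer ids.
#' @return object of class `direction_panel`.
#' @export
direction_panel <- function(sx, sy, valid = NULL, subjects = NULL) {
  sx <- as.matrix(sx); sy <- as.matrix(sy)
  if (!all(dim(sx) == dim(sy))) stop("sx and sy must share dimensions")
  if (is.null(valid)) valid <- !(is.na(sx) | is.na(sy))
  valid <- valid & !(is.na(sx) | is.na(sy))
  norms <- sqrt(sx^2 + sy^2)
  bad <- valid & abs(norms - 1) > 1e-9
  if (any(bad, na.rm = TRUE)) stop("valid directions must be unit vectors")
  if (is.null(subjects)) subjects <- paste0("s", seq_len(ncol(sx)))
  structure(
    list(sx = unname(sx), sy = unname(sy), valid = unname(valid),
         subjects = as.character(subjects)),
    class = "direction_panel"
  )
}

#' @export
print.direction_panel <- function(x, ...) {
  cat(sprintf("<direction_panel> %d viewers x %d samples, %.1f%% valid\n",
              ncol(x$sx), nrow(x$sx), 100 * mean(x$valid)))
  invisible(x)
}

#' Mean direction vectors per viewer
#'
#' \eqn{\mu_i = \langle \sigma_i(t) \rangle_t} over each viewer's valid
#' samples. `|mu_i| <= 1` always; near zero for isotropic gaze.
#'
#' @param dirs a [direction_panel].
#' @return N x 2 matrix of mean directions (NA rows for viewers with no
#'   valid samples).
#' @export
panel_mu <- function(dirs) {
  stopifnot(inherits(dirs, "direction_panel"))
  n <- ncol(dirs$sx)
  mu <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    v <- dirs$valid[, i]
    if (any(v)) mu[i, ] <- c(mean(dirs$sx[v, i]), mean(dirs$sy[v, i]))
  }
  mu
}
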