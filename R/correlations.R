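#' Inter-subject correlation of gaze position
#'
#' Pearson correlation of horizontal (and vertical) gaze position between
#' every pair of viewers, computed over the samples at which both viewers
#' are non-missing, then averaged across all pairs:
#' \deqn{C_x = \frac{1}{N(N-1)} \sum_i \sum_{j \ne i} \mathrm{corr}(x_i, x_j).}
#' Pairs with a constant trajectory (undefined correlation) or fewer than
#' `min_joint` joint samples are skipped and recorded.
#'
#' @param panel a [gaze_panel] with at least 2 viewers.
#' @param min_joint minimum jointly valid samples per pair (default 2).
#' @return named vector `c(C_x = , C_y = )`; skipped pairs in attribute
#'   `skipped`.
#' @export
position_isc <- function(panel, min_joint = 2) {
  stopifnot(inherits(panel, "gaze_panel"))
  n <- ncol(panel$x)
  if (n < 2) stop("need at least 2 subjects")
  ok <- !panel$missing
  rx <- c(); ry <- c(); skipped <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      joint <- ok[, i] & ok[, j]
      if (sum(joint) < min_joint) {
        skipped <- c(skipped, sprintf("%s-%s (joint n = %d)",
                                      panel$subjects[i], panel$subjects[j],
                                      sum(joint)))
        next
      }
      cx <- suppressWarnings(stats::cor(panel$x[joint, i], panel$x[joint, j]))
      cy <- suppressWarnings(stats::cor(panel$y[joint, i], panel$y[joint, j]))
      if (is.na(cx) || is.na(cy)) {
        skipped <- c(skipped, sprintf("%s-%s (constant trajectory)",
                                      panel$subjects[i], panel$subjects[j]))
        next
      }
      rx <- c(rx, cx); ry <- c(ry, cy)
    }
  }
  if (length(rx) == 0) stop("no valid pairs for position ISC")
  out <- c(C_x = mean(rx), C_y = mean(ry))
  attr(out, "skipped") <- skipped
  out
}

#' Pairwise connected correlations of eye-movement direction
#'
#' For each viewer pair the connected correlation
#' \deqn{C_{ij} = \langle \sigma_i(t)\cdot\sigma_j(t)\rangle_t -
#'   \mu_i\cdot\mu_j,}
#' with the time average over jointly valid samples and \eqn{\mu_i} each
#' viewer's own mean direction. The pair average
#' \eqn{C_\sigma = \frac{1}{N(N-1)}\sum_{i\ne j} C_{ij}} is the
#' susceptibility of the viewer ensemble — maximal near the critical point.
#'
#' @param dirs a [direction_panel] with at least 2 viewers.
#' @param min_joint minimum jointly valid samples for a pair (default 100);
#'   pairs below it get `NA` and are excluded from `C_sigma`.
#' @return list of class `correlation_set`: `C_pairwise` (symmetric, `NA`
#'   diagonal), `C_sigma`, `mu` (N x 2), `n_joint` (pair sample counts),
#'   `subjects`.
#' @export
direction_correlations <- function(dirs, min_joint = 100) {
  stopifnot(inherits(dirs, "direction_panel"))
  n <- ncol(dirs$sx)
  if (n < 2) stop("need at least 2 subjects")
  mu <- panel_mu(dirs)
  C <- matrix(NA_real_, n, n)
  n_joint <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      joint <- dirs$valid[, i] & dirs$valid[, j]
      n_joint[i, j] <- n_joint[j, i] <- sum(joint)
      if (sum(joint) < min_joint) next
      dotm <- mean(dirs$sx[joint, i] * dirs$sx[joint, j] +
                     dirs$sy[joint, i] * dirs$sy[joint, j])
      C[i, j] <- C[j, i] <- dotm - sum(mu[i, ] * mu[j, ])
    }
  }
  off <- C[upper.tri(C)]
  if (all(is.na(off))) stop("no pair has enough jointly valid samples")
  structure(
    list(C_pairwise = C, C_sigma = mean(off, na.rm = TRUE), mu = mu,
         n_joint = n_joint, subjects = dirs$subjects),
    class = "correlation_set"
  )
}

#' @export
print.correlation_set <- function(x, ...) {
  off <- x$C_pairwise[upper.tri(x$C_pairwise)]
  cat(sprintf("<correlation_set> %d viewers, C_sigma = %.4f (%d/%d pairs)\n",
              length(x$subjects), x$C_sigma, sum(!is.na(off)), length(off)))
  invisible(x)
}

#' Rating homophily of a viewer group
#'
#' Pairwise agreement of preference ratings,
#' \deqn{O = \frac{1}{N(N-1)} \sum_{i=1}^N \sum_{j\ne i}
#'   \left(1 - \frac{|p_i - p_j|}{p_{max}}\right),}
#' equal to 1 when all viewers agree exactly and approaching 0.5 for the
#' worst-case even split between the scale extremes (exactly
#' \eqn{(N-2)/(2(N-1))} for an even N half rating `p_max` and half rating 0).
#'
#' @param ratings numeric vector of preference ratings, one per viewer.
#' @param p_max scale maximum (default 10).
#' @return scalar homophily.
#' @export
homophily <- function(ratings, p_max = 10) {
  if (!is.numeric(p_max) || p_max <= 0) stop("p_max must be positive")
  ratings <- as.numeric(ratings)
  n <- length(ratings)
  if (n < 2) stop("need at least 2 raters")
  if (any(is.na(ratings)) || any(ratings < 0 | ratings > p_max))
    stop("ratings must lie in [0, p_max]")
  d <- abs(outer(ratings, ratings, `-`)) / p_max
  1 - sum(d) / (n * (n - 1))
}

#' Pearson correlation with a two-sided p-value
#'
#' Thin wrapper over the t-distribution Pearson test used for all reported
#' pairings; pairs with a missing value in either input are dropped.
#'
#' @param xs,ys paired numeric vectors.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(xs, ys) {
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("zero-variance input: correlation undefined")
  ct <- stats::cor.test(xs, ys, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xs))
}
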