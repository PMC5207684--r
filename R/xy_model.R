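#' Fully connected XY model of viewer interactions
#'
#' Container for the maximum-entropy model of eye-movement directions: a set
#' of N two-dimensional unit "spins" (one per viewer) with pairwise alignment
#' couplings `J[i, j]`, external fields `h[i, ]`, and a temperature. The
#' model energy is
#' \deqn{E(\sigma) = -\sum_i h_i \cdot \sigma_i -
#'       \sum_{i<j} J_{ij}\, \sigma_i \cdot \sigma_j,}
#' and states are Boltzmann-distributed, \eqn{P_T(\sigma) \propto
#' \exp(-E(\sigma)/T)}. At the operating temperature \eqn{T = 1} this is
#' exactly the maximum-entropy distribution matching the observed mean
#' directions and pairwise connected correlations.
#'
#' @param J symmetric numeric coupling matrix; the diagonal is forced to zero
#'   (self-interactions are excluded by convention).
#' @param h per-viewer field, an N x 2 matrix (or `NULL` for zero fields).
#' @param temperature positive scalar; 1 is the operating temperature at
#'   which the fitted model reproduces the data moments.
#' @param subjects optional character vector of viewer ids.
#' @return An object of class `xy_model`.
#' @export
xy_model <- function(J, h = NULL, temperature = 1, subjects = NULL) {
  J <- as.matrix(J)
  n <- nrow(J)
  if (ncol(J) != n) stop("J must be square")
  if (!isTRUE(all.equal(J, t(J), tolerance = 1e-8, check.attributes = FALSE)))
    stop("J must be symmetric")
  J <- (J + t(J)) / 2
  diag(J) <- 0
  if (is.null(h)) h <- matrix(0, n, 2)
  h <- as.matrix(h)
  if (nrow(h) != n || ncol(h) != 2) stop("h must be an N x 2 matrix")
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("temperature must be a positive scalar")
  if (is.null(subjects)) subjects <- paste0("s", seq_len(n))
  if (length(subjects) != n) stop("subjects must have one id per row of J")
  structure(
    list(J = unname(J), h = unname(h), temperature = temperature,
         n_subjects = n, subjects = as.character(subjects)),
    class = "xy_model"
  )
}

#' @export
print.xy_model <- function(x, ...) {
  off <- x$J[upper.tri(x$J)]
  cat(sprintf("<xy_model> %d spins, T = %g\n", x$n_subjects, x$temperature))
  cat(sprintf("  mean |J_ij| = %.4g, max J_ij = %.4g, mean |h| = %.4g\n",
              mean(abs(off)), if (length(off)) max(off) else NA_real_,
              mean(sqrt(rowSums(x$h^2)))))
  invisible(x)
}

#' Energy of an XY-model state
#'
#' Evaluates \eqn{E = -\sum_i h_i\cdot\sigma_i - \sum_{i<j} J_{ij}
#' \sigma_i\cdot\sigma_j} for one configuration of unit direction vectors.
#'
#' @param model an [xy_model].
#' @param state N x 2 matrix of unit 2-vectors (rows are spins).
#' @return scalar energy (dimensionless).
#' @export
xy_energy <- function(model, state) {
  stopifnot(inherits(model, "xy_model"))
  state <- as.matrix(state)
  if (nrow(state) != model$n_subjects || ncol(state) != 2)
    stop("state must be an N x 2 matrix of unit vectors")
  norms <- sqrt(rowSums(state^2))
  if (any(abs(norms - 1) > 1e-6)) stop("state rows must be unit vectors")
  G <- state %*% t(state)                    # sigma_i . sigma_j
  -sum(model$h * state) - sum(G[upper.tri(G)] * model$J[upper.tri(model$J)])
}

# Internal: run the Metropolis sampler and return moment estimates.
# dot  = <sigma_i . sigma_j>, mu = <sigma_i>, e_mean/e2_mean of the energy.
xy_moments <- function(model, n_samples, seed,
                       burn_sweeps = 100L * model$n_subjects,
                       thin_sweeps = 10L, temperature = model$temperature,
                       keep_samples = FALSE) {
  if (temperature <= 0) stop("temperature must be positive")
  xy_mcmc_cpp(model$J, model$h, temperature,
              as.integer(n_samples), as.integer(burn_sweeps),
              as.integer(thin_sweeps), 1.0, as.double(seed %% 2^31),
              keep_samples, TRUE)
}

#' Sample direction configurations from the Boltzmann distribution
#'
#' Draws equilibrated, thinned samples of N unit direction vectors from
#' \eqn{P_T(\sigma)\propto\exp(-E(\sigma)/T)} using a single-site Metropolis
#' kernel (angle proposals tuned to roughly 50\% acceptance during burn-in).
#' Successive retained samples are separated by `thin_sweeps` full sweeps so
#' that they are approximately independent.
#'
#' @param model an [xy_model]; its `temperature` is used.
#' @param n_samples number of retained configurations.
#' @param seed integer seed; identical seeds give identical output.
#' @param burn_sweeps equilibration sweeps before sampling
#'   (default `100 * N`).
#' @param thin_sweeps sweeps between retained samples (default 10).
#' @return A [direction_panel] with one row per retained sample and all
#'   samples valid.
#' @export
xy_sample <- function(model, n_samples, seed,
                      burn_sweeps = 100L * model$n_subjects,
                      thin_sweeps = 10L) {
  stopifnot(inherits(model, "xy_model"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  res <- xy_moments(model, n_samples, seed, burn_sweeps, thin_sweeps,
                    keep_samples = TRUE)
  direction_panel(res$sx, res$sy,
                  valid = matrix(TRUE, nrow(res$sx), ncol(res$sx)),
                  subjects = model$subjects)
}

#' Infer the maximum-entropy XY model by Monte Carlo Boltzmann learning
#'
#' Finds couplings `J` and fields `h` whose Boltzmann distribution at the
#' operating temperature T = 1 reproduces the observed pairwise connected
#' correlations `C[i, j]` and mean directions `mu[i, ]`. Starting from
#' `J = 0, h = 0`, each iteration samples the current model and nudges the
#' parameters along the moment mismatch:
#' \deqn{J_{ij} \leftarrow J_{ij} + \eta_J (C^{data}_{ij} - C^{model}_{ij}),
#' \quad h_i \leftarrow h_i + \eta_h (\mu^{data}_i - \mu^{model}_i).}
#' Learning rates decay geometrically and the per-iteration Monte Carlo
#' sample size grows slowly, so late iterations average over more draws.
#' Convergence is declared when the Pearson correlation ("fidelity") between
#' model and data off-diagonal correlations reaches `fidelity_target`.
#'
#' Pairs whose target correlation is `NA` (dropped upstream for insufficient
#' joint samples) are excluded from the update and their couplings stay
#' frozen at zero.
#'
#' @param C_target symmetric matrix of connected direction correlations
#'   (diagonal ignored); `NA` entries mark missing pairs.
#' @param mu_target N x 2 matrix of mean directions (or `NULL` for zero).
#' @param seed integer seed controlling all Monte Carlo draws.
#' @param eta_J,eta_h initial learning rates.
#' @param decay geometric decay factor applied to both rates per iteration.
#' @param n_samples Monte Carlo samples in the first iteration; grows by
#'   `sample_growth` per iteration up to `max_samples`.
#' @param max_iter iteration cap; the fit report is returned either way.
#' @param fidelity_target stop once model-vs-data correlation fidelity
#'   reaches this value (default 0.99).
#' @param lambda optional L2 shrinkage on J (0 = none, the default).
#' @param thin_sweeps,burn_sweeps Metropolis controls per iteration.
#' @param verbose print progress every 25 iterations.
#' @return list with elements `model` (the fitted [xy_model]) and `report`
#'   (iterations run, fidelity trace, final mean-direction error, learning
#'   rate trace, `converged` flag).
#' @export
fit_xy <- function(C_target, mu_target = NULL, seed = 1L,
                   eta_J = 0.3, eta_h = 0.1, decay = 0.997,
                   n_samples = 1500L, sample_growth = 1.02,
                   max_samples = 20000L, max_iter = 500L,
                   fidelity_target = 0.99, lambda = 0,
                   thin_sweeps = 5L, burn_sweeps = NULL,
                   verbose = FALSE) {
  C_target <- as.matrix(C_target)
  n <- nrow(C_target)
  if (ncol(C_target) != n) stop("C_target must be square")
  offd <- upper.tri(C_target)
  if (!isTRUE(all.equal(C_target[offd], t(C_target)[offd], tolerance = 1e-8)))
    stop("C_target must be symmetric")
  if (any(!is.finite(C_target[offd]) & !is.na(C_target[offd])))
    stop("C_target must be finite or NA")
  if (is.null(mu_target)) mu_target <- matrix(0, n, 2)
  mu_target <- as.matrix(mu_target)
  if (any(sqrt(rowSums(mu_target^2)) > 1 + 1e-8))
    stop("mean directions must have |mu_i| <= 1")
  if (is.null(burn_sweeps)) burn_sweeps <- 100L * n

  usable <- !is.na(C_target) & offd
  if (!any(usable)) stop("no usable target correlations")

  J <- matrix(0, n, n)
  h <- matrix(0, n, 2)
  fid_trace <- numeric(0)
  lr_trace <- numeric(0)
  mu_err <- NA_real_
  converged <- FALSE
  n_drop <- 0L

  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    m <- as.integer(min(max_samples, n_samples * sample_growth^(iter - 1)))
    mom <- xy_moments(xy_model(J, h, 1), m, seed = seed + iter,
                      burn_sweeps = if (iter == 1L) burn_sweeps
                                    else as.integer(burn_sweeps / 4),
                      thin_sweeps = thin_sweeps)
    C_model <- mom$dot - mom$mu %*% t(mom$mu)
    fid <- suppressWarnings(stats::cor(C_target[usable], C_model[usable]))
    fid_trace <- c(fid_trace, fid)
    lr <- eta_J * decay^(iter - 1)
    lr_trace <- c(lr_trace, lr)
    mu_err <- mean(sqrt(rowSums((mu_target - mom$mu)^2)))

    if (is.finite(fid) && fid >= fidelity_target) {
      converged <- TRUE
      break
    }
    # persistent-divergence guard: a once-meaningful fidelity falling well
    # below its best for many consecutive iterations signals a runaway
    # learning rate (noise-level fidelity on near-zero targets is exempt)
    if (length(fid_trace) > 60) {
      best <- cummax(ifelse(is.finite(fid_trace), fid_trace, -1))
      recent <- utils::tail(fid_trace - best, 30)
      if (max(best) > 0.6 && all(is.finite(recent)) && all(recent < -0.25)) {
        cnd <- simpleError(paste0(
          "Boltzmann learning diverged: fidelity decreasing persistently ",
          "(best ", round(max(best), 3), ", last ",
          round(utils::tail(fid_trace, 1), 3),
          "); diagnostic trace in conditions$fidelity_trace"))
        cnd$fidelity_trace <- fid_trace
        stop(cnd)
      }
    }

    dC <- C_target - C_model
    dC[!usable & !t(usable)] <- 0
    dC[is.na(dC)] <- 0
    step_J <- lr * (dC + t(dC)) / 2
    J <- J + step_J - lambda * J
    diag(J) <- 0
    h <- h + (eta_h * decay^(iter - 1)) * (mu_target - mom$mu)
    if (verbose && iter %% 25 == 0)
      message(sprintf("iter %d: fidelity %.4f (m = %d)", iter, fid, m))
  }

  report <- list(iterations = iter, fidelity = utils::tail(fid_trace, 1),
                 fidelity_trace = fid_trace, mu_error = mu_err,
                 lr_trace = lr_trace, converged = converged)
  list(model = xy_model(J, h, 1), report = report)
}

#' Average fitted models and thermodynamic scans over 30-s segments
#'
#' Long videos are analysed in independent segments; per-video quantities
#' (couplings, critical temperatures, scalars) are the element-wise means
#' over segments. When segments retain different subject subsets, the
#' intersection of subjects is used.
#'
#' @param models list of [xy_model] objects, one per segment.
#' @param scans optional list of [thermo_scan] objects (same length).
#' @return list with `J` (mean coupling matrix), `h`, `subjects`, and, when
#'   scans are given, `T_c` and `T_c_eigen` means (NA scans are dropped).
#' @export
average_over_segments <- function(models, scans = NULL) {
  if (length(models) == 0) stop("empty model list")
  stopifnot(all(vapply(models, inherits, logical(1), "xy_model")))
  common <- Reduce(intersect, lapply(models, `[[`, "subjects"))
  if (length(common) == 0) stop("no common subjects across segments")
  Js <- lapply(models, function(m) {
    idx <- match(common, m$subjects)
    m$J[idx, idx, drop = FALSE]
  })
  hs <- lapply(models, function(m) {
    idx <- match(common, m$subjects)
    m$h[idx, , drop = FALSE]
  })
  out <- list(J = Reduce(`+`, Js) / length(Js),
              h = Reduce(`+`, hs) / length(hs),
              subjects = common, n_segments = length(models))
  if (!is.null(scans)) {
    tc <- vapply(scans, function(s) s$T_c %||% NA_real_, numeric(1))
    out$T_c <- if (all(is.na(tc))) NA_real_ else mean(tc, na.rm = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
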