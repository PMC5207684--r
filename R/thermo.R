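#' Heat capacity of a fitted model at one temperature
#'
#' Samples the Boltzmann distribution of the model at temperature `T` and
#' returns the heat capacity from the energy-fluctuation formula
#' \deqn{C_V(T) = \frac{\langle E^2\rangle - \langle E\rangle^2}{T^2},}
#' together with the energy mean and variance. Equivalent (up to Monte Carlo
#' error) to the temperature derivative of the mean energy.
#'
#' @param model an [xy_model]; its own `temperature` is ignored in favour of
#'   `temperature`.
#' @param temperature evaluation temperature (> 0).
#' @param n_samples,thin_sweeps,burn_sweeps Monte Carlo budget.
#' @param seed integer seed.
#' @return list with `C_V`, `energy_mean`, `energy_var`, `se` (approximate
#'   Monte Carlo standard error of `C_V`).
#' @export
heat_capacity <- function(model, temperature, n_samples = 4000L, seed = 1L,
                          thin_sweeps = 10L,
                          burn_sweeps = 100L * model$n_subjects) {
  stopifnot(inherits(model, "xy_model"))
  if (temperature <= 0) stop("temperature must be positive")
  mom <- xy_moments(model, n_samples, seed, burn_sweeps, thin_sweeps,
                    temperature = temperature, keep_samples = TRUE)
  e_var <- mom$e2_mean - mom$e_mean^2
  # crude SE of the variance for approximately independent thinned samples:
  # var(s^2) ~ (m4 - m2^2)/n
  E <- energy_series(model, mom$sx, mom$sy)
  m2 <- stats::var(E)
  m4 <- mean((E - mean(E))^4)
  se <- sqrt(max(0, m4 - m2^2) / length(E)) / temperature^2
  list(C_V = e_var / temperature^2, energy_mean = mom$e_mean,
       energy_var = e_var, se = se)
}

# energies of a matrix of sampled configurations (rows = samples),
# vectorised: pair term = 1/2 sum_ij J_ij sigma_i.sigma_j per row
energy_series <- function(model, sx, sy) {
  field <- sx %*% model$h[, 1] + sy %*% model$h[, 2]
  pair <- (rowSums((sx %*% model$J) * sx) + rowSums((sy %*% model$J) * sy)) / 2
  as.numeric(-field - pair)
}

#' Heat-capacity curve over a temperature sweep and critical temperature
#'
#' Evaluates \eqn{C_V(T)} on a grid (22 points on \[0.17, 1.43\] by default)
#' and locates the critical temperature at the peak of the curve. To be
#' robust to Monte Carlo noise the peak is taken from a local quadratic fit
#' around the argmax of a 3-point moving average; a curve with no peak above
#' noise (flat within `flat_tol` relative variation) yields `T_c = NA` with
#' a diagnostic.
#'
#' Interpretation: the operating temperature is 1 by construction, so
#' `T_c < 1` places the observed system on the disordered ("liquid") side
#' and `T_c > 1` on the ordered side.
#'
#' @param model an [xy_model] fitted at the operating temperature.
#' @param t_min,t_max,n_points temperature grid.
#' @param n_samples Monte Carlo samples per grid point.
#' @param seed integer seed.
#' @param flat_tol relative C_V variation under which the curve is declared
#'   flat.
#' @param thin_sweeps Metropolis thinning per grid point.
#' @return object of class `thermo_scan`: data.frame `grid`
#'   (`temperature`, `C_V`, `energy_mean`, `energy_var`), `T_c`, `T_o = 1`,
#'   `phase` ("liquid", "ordered", "critical" or "undefined"), `note`.
#' @export
scan_temperatures <- function(model, t_min = 0.17, t_max = 1.43,
                              n_points = 22L, n_samples = 3000L, seed = 1L,
                              flat_tol = 0.05, thin_sweeps = 10L) {
  stopifnot(inherits(model, "xy_model"))
  if (t_min <= 0 || t_max <= t_min) stop("need 0 < t_min < t_max")
  if (n_points < 5) stop("grid must have at least 5 points")
  temps <- seq(t_min, t_max, length.out = n_points)
  rows <- lapply(seq_along(temps), function(k) {
    hc <- heat_capacity(model, temps[k], n_samples = n_samples,
                        seed = seed + k, thin_sweeps = thin_sweeps)
    data.frame(temperature = temps[k], C_V = hc$C_V,
               energy_mean = hc$energy_mean, energy_var = hc$energy_var,
               se = hc$se)
  })
  grid <- do.call(rbind, rows)
  pk <- locate_peak(grid$temperature, grid$C_V, grid$se, flat_tol)
  phase <- if (is.na(pk$T_c)) "undefined"
           else if (abs(pk$T_c - 1) < diff(temps[1:2])) "critical"
           else if (pk$T_c < 1) "liquid" else "ordered"
  structure(
    list(grid = grid, T_c = pk$T_c, T_o = 1, phase = phase, note = pk$note),
    class = "thermo_scan"
  )
}

# Peak location under MC noise: 3-point moving average, then a local
# quadratic fit around the smoothed argmax. Flat curves -> NA.
locate_peak <- function(temps, cv, se = NULL, flat_tol = 0.05) {
  n <- length(cv)
  sm <- cv
  if (n >= 3) sm[2:(n - 1)] <- (cv[1:(n - 2)] + cv[2:(n - 1)] + cv[3:n]) / 3
  rng <- max(sm) - min(sm)
  noise <- if (!is.null(se)) 2 * stats::median(se) else 0
  if (rng <= max(flat_tol * max(abs(sm)), noise))
    return(list(T_c = NA_real_, note = "flat heat-capacity curve: no peak above noise"))
  k <- which.max(sm)
  idx <- max(1, k - 1):min(n, k + 1)
  if (length(idx) < 3 || k == 1 || k == n)
    return(list(T_c = temps[k],
                note = if (k == 1) "peak at grid minimum" else
                       if (k == n) "peak at grid maximum" else ""))
  fit <- stats::lm(sm[idx] ~ poly(temps[idx], 2, raw = TRUE))
  b <- stats::coef(fit)
  tc <- if (is.na(b[3]) || b[3] >= 0) temps[k] else -b[2] / (2 * b[3])
  tc <- min(max(tc, temps[1]), temps[n])
  list(T_c = unname(tc), note = "")
}

#' @export
print.thermo_scan <- function(x, ...) {
  cat(sprintf("<thermo_scan> %d temperatures in [%.3g, %.3g]; T_c = %s (%s)\n",
              nrow(x$grid), min(x$grid$temperature), max(x$grid$temperature),
              if (is.na(x$T_c)) "undefined" else sprintf("%.3f", x$T_c),
              x$phase))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Mean-field critical-temperature estimate from the coupling spectrum
#'
#' Fast proxy for the Monte Carlo critical temperature: for the
#' two-component (XY) mean-field model the instability of the disordered
#' phase occurs at \eqn{T = \lambda_{max}(J)/2}, with
#' \eqn{\lambda_{max}} the largest eigenvalue of the coupling matrix. The
#' estimate is not equal to the Monte Carlo `T_c` but correlates strongly
#' with it, making it useful for screening.
#'
#' @param model an [xy_model] (or bare symmetric coupling matrix).
#' @return scalar estimate \eqn{\lambda_{max}(J)/2}.
#' @export
tc_from_eigenvalue <- function(model) {
  J <- if (inherits(model, "xy_model")) model$J else as.matrix(model)
  if (!isTRUE(all.equal(J, t(J), tolerance = 1e-8, check.attributes = FALSE)))
    stop("J must be symmetric")
  max(eigen(J, symmetric = TRUE, only.values = TRUE)$values) / 2
}
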