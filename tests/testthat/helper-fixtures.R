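# Shared fixtures and independent oracles, built in code at test time.

# Two-spin XY oracle by 1-D numerical quadrature over the angle difference:
# <cos phi> under weight exp(k cos phi) equals I1(k)/I0(k).
bessel_ratio_oracle <- function(k) {
  num <- stats::integrate(function(p) cos(p) * exp(k * cos(p)), -pi, pi)$value
  den <- stats::integrate(function(p) exp(k * cos(p)), -pi, pi)$value
  num / den
}

# Quadrature moments of the two-spin energy E = -J cos(phi) at temperature T.
two_spin_energy_oracle <- function(J, temperature) {
  k <- J / temperature
  den <- stats::integrate(function(p) exp(k * cos(p)), -pi, pi)$value
  e1 <- stats::integrate(function(p) -J * cos(p) * exp(k * cos(p)),
                         -pi, pi)$value / den
  e2 <- stats::integrate(function(p) (J * cos(p))^2 * exp(k * cos(p)),
                         -pi, pi)$value / den
  list(e_mean = e1, e_var = e2 - e1^2,
       c_v = (e2 - e1^2) / temperature^2)
}

# Simple deterministic gaze panel: straight-line motion with per-subject
# angle, optional noise.
make_line_panel <- function(n_t = 200, angles = c(0, pi / 4), rate = 250,
                            speed = 5, noise_sd = 0, seed = 1) {
  set.seed(seed)
  n_s <- length(angles)
  tt <- (seq_len(n_t) - 1) * 1000 / rate
  x <- sapply(angles, function(a) seq_len(n_t) * speed * cos(a)) +
    matrix(rnorm(n_t * n_s, sd = noise_sd), n_t, n_s)
  y <- sapply(angles, function(a) seq_len(n_t) * speed * sin(a)) +
    matrix(rnorm(n_t * n_s, sd = noise_sd), n_t, n_s)
  gaze_panel(tt, x, y)
}

# Direction panel with exact planted series (list of T x N component mats).
make_direction_panel <- function(sx, sy) {
  direction_panel(as.matrix(sx), as.matrix(sy))
}

# Random angles -> unit vector components
angles_to_dirs <- function(theta) list(sx = cos(theta), sy = sin(theta))

# Two-clique coupling matrix joined by one bridge of given weight.
two_clique_J <- function(clique_size = 4, within = 1, bridge = 0.5) {
  n <- 2 * clique_size
  J <- matrix(0, n, n)
  g1 <- seq_len(clique_size); g2 <- clique_size + g1
  J[g1, g1] <- within; J[g2, g2] <- within
  diag(J) <- 0
  J[clique_size, clique_size + 1] <- bridge
  J[clique_size + 1, clique_size] <- bridge
  J
}

# Adjacency of k disconnected cliques of size s.
clique_adjacency <- function(k = 2, s = 4) {
  n <- k * s
  A <- matrix(0, n, n)
  for (c in seq_len(k)) {
    idx <- ((c - 1) * s + 1):(c * s)
    A[idx, idx] <- 1
  }
  diag(A) <- 0
  A
}
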