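#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Deterministic, platform-stable RNG (splitmix64-seeded xoshiro256+).
// The sampler must reproduce bit-identically under a given seed regardless
// of the host libstdc++, so we avoid std::uniform_real_distribution.
namespace {

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the seed into four state words
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }
};

}  // namespace

// Single-site Metropolis sampler for the fully connected XY model
//   E(sigma) = -sum_i h_i . sigma_i - sum_{i<j} J_ij sigma_i . sigma_j
// at temperature T, with sigma_i a unit 2-vector parameterised by angle.
// Proposal: theta' = theta + Uniform(-width, width); width is tuned during
// burn-in toward ~50% acceptance when adapt = true.
//
// Returns thinned samples (optional) and running moments:
//   dot[i][j]  = <sigma_i . sigma_j> over retained samples
//   mu[i]      = <sigma_i> (2-vector)
//   e_mean, e2_mean over retained samples
// [[Rcpp::export]]
List xy_mcmc_cpp(NumericMatrix J, NumericMatrix h, double temperature,
                 int n_samples, int burn_sweeps, int thin_sweeps,
                 double prop_width, double seed, bool keep_samples,
                 bool adapt) {
  const int N = J.nrow();
  if (J.ncol() != N) stop("J must be square");
  if (h.nrow() != N || h.ncol() != 2) stop("h must be N x 2");
  if (temperature <= 0) stop("temperature must be positive");
  if (n_samples < 1) stop("n_samples must be >= 1");
  if (thin_sweeps < 1) thin_sweeps = 1;

  Xoshiro256 rng(static_cast<uint64_t>(seed));

  std::vector<double> theta(N), sx(N), sy(N);
  for (int i = 0; i < N; ++i) {
    theta[i] = 2.0 * M_PI * rng.unif();
    sx[i] = std::cos(theta[i]);
    sy[i] = std::sin(theta[i]);
  }

  double width = prop_width > 0 ? prop_width : 1.0;
  long acc = 0, tries = 0;
  long acc_win = 0, tries_win = 0;

  auto sweep = [&](bool tuning) {
    for (int i = 0; i < N; ++i) {
      // local field on spin i
      double fx = h(i, 0), fy = h(i, 1);
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        const double Jij = J(i, j);
        if (Jij != 0.0) {
          fx += Jij * sx[j];
          fy += Jij * sy[j];
        }
      }
      const double th_new = theta[i] + width * (2.0 * rng.unif() - 1.0);
      const double nx = std::cos(th_new), ny = std::sin(th_new);
      const double dE = -(fx * (nx - sx[i]) + fy * (ny - sy[i]));
      ++tries;
      if (tuning) ++tries_win;
      if (dE <= 0.0 || rng.unif() < std::exp(-dE / temperature)) {
        theta[i] = th_new;
        sx[i] = nx;
        sy[i] = ny;
        ++acc;
        if (tuning) ++acc_win;
      }
    }
  };

  // burn-in with optional width adaptation every 50 sweeps
  for (int s = 0; s < burn_sweeps; ++s) {
    sweep(adapt);
    if (adapt && ((s + 1) % 50 == 0) && tries_win > 0) {
      const double rate = static_cast<double>(acc_win) / tries_win;
      if (rate > 0.55) width = std::min(width * 1.15, M_PI);
      else if (rate < 0.45) width = std::max(width * 0.85, 1e-3);
      acc_win = 0;
      tries_win = 0;
    }
  }

  NumericMatrix dot(N, N), mu(N, 2);
  NumericMatrix samp_x, samp_y;
  if (keep_samples) {
    samp_x = NumericMatrix(n_samples, N);
    samp_y = NumericMatrix(n_samples, N);
  }
  double e_sum = 0.0, e2_sum = 0.0;

  for (int s = 0; s < n_samples; ++s) {
    for (int k = 0; k < thin_sweeps; ++k) sweep(false);

    double E = 0.0;
    for (int i = 0; i < N; ++i) {
      E -= h(i, 0) * sx[i] + h(i, 1) * sy[i];
      mu(i, 0) += sx[i];
      mu(i, 1) += sy[i];
      for (int j = i + 1; j < N; ++j) {
        const double d = sx[i] * sx[j] + sy[i] * sy[j];
        dot(i, j) += d;
        E -= J(i, j) * d;
      }
      if (keep_samples) {
        samp_x(s, i) = sx[i];
        samp_y(s, i) = sy[i];
      }
    }
    e_sum += E;
    e2_sum += E * E;
  }

  const double inv = 1.0 / n_samples;
  for (int i = 0; i < N; ++i) {
    mu(i, 0) *= inv;
    mu(i, 1) *= inv;
    dot(i, i) = 1.0;
    for (int j = i + 1; j < N; ++j) {
      dot(i, j) *= inv;
      dot(j, i) = dot(i, j);
    }
  }

  List out = List::create(
      _["dot"] = dot, _["mu"] = mu, _["e_mean"] = e_sum * inv,
      _["e2_mean"] = e2_sum * inv,
      _["acceptance"] = tries > 0 ? static_cast<double>(acc) / tries : NA_REAL,
      _["prop_width"] = width);
  if (keep_samples) {
    out["sx"] = samp_x;
    out["sy"] = samp_y;
  }
  return out;
}
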