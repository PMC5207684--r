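---
title: "Thermodynamics of collective gaze: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of collective gaze: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a group of people watches the same video, their eye movements are not
independent: well-produced material pulls gaze trajectories into partial
alignment, and the degree of alignment carries information about how the
audience judges the material. `gazetherm` provides a complete pipeline for
quantifying this collective behaviour from multi-viewer eye-tracking
recordings:

1. **Inter-subject correlation (ISC)** of gaze position and of eye-movement
   *direction* across all viewer pairs;
2. a **maximum-entropy interaction model** — the fully connected XY model —
   fitted so that its stationary distribution reproduces the observed mean
   directions and pairwise connected correlations;
3. a **thermodynamic analysis** of the fitted model: heat-capacity curves
   over a temperature sweep locate a critical temperature $T_c$ that measures
   how close the audience is to a collective ordering transition;
4. **community structure** of the inferred interaction network (percolation
   threshold, modularity, community detection);
5. **rating homophily**, the pairwise agreement of the viewers' preference
   ratings.

Because eye-tracking recordings of this kind are rarely shareable, the
package also ships a first-class synthetic-data generator that produces gaze
panels, direction series and ratings with *planted* interaction structure,
so every downstream stage can be validated against a known ground truth.

## The model

Each viewer $i$ contributes a time series of eye-movement directions, unit
2-vectors $\sigma_i(t) = v_i(t)/|v_i(t)|$ with
$v_i(t) = \tfrac12\left(r_i(t+1) - r_i(t-1)\right)$ the central-difference
velocity of the gaze position $r_i(t)$. Directions rather than positions
are modelled for two reasons: direction emphasises the reorienting of
attention, and dot products of unit vectors give a translation-invariant,
bounded interaction energy.

The observed statistics are the mean directions $\mu_i = \langle
\sigma_i(t)\rangle_t$ and the connected pairwise correlations

$$C_{ij} = \langle \sigma_i(t)\cdot\sigma_j(t)\rangle_t - \mu_i\cdot\mu_j,$$

averaged into the susceptibility $C_\sigma = \frac{1}{N(N-1)}\sum_{i\neq j}
C_{ij}$. The least-structured distribution reproducing $\{\mu_i, C_{ij}\}$
is the Boltzmann distribution of a fully connected XY model,

$$E(\sigma) = -\sum_i h_i\cdot\sigma_i - \sum_{i<j} J_{ij}\,
\sigma_i\cdot\sigma_j, \qquad
P_T(\sigma) \propto e^{-E(\sigma)/T},$$

at the *operating temperature* $T_o = 1$. Positive $J_{ij}$ favours
alignment of the two viewers' directions. (A sign slip exists in some
statements of the maximum-entropy distribution in the source literature;
this package uses the Boltzmann convention throughout: probability
$\propto \exp(-E/T)$ with the energy above, so positive couplings mean
alignment.) The couplings are interpreted as *interactions*: unlike
$C_{ij}$, which is promiscuous (two viewers correlate if both resemble a
third), $J_{ij}$ captures the conditional dependence uniquely shared by the
pair.

## Inference: Monte Carlo Boltzmann learning

`fit_xy()` starts from $J = 0$, $h = 0$ and iterates

$$J_{ij} \leftarrow J_{ij} + \eta_J\,(C^{\text{data}}_{ij} -
C^{\text{model}}_{ij}), \qquad
h_i \leftarrow h_i + \eta_h\,(\mu^{\text{data}}_i - \mu^{\text{model}}_i),$$

with model moments estimated by single-site Metropolis sampling at $T = 1$.
Convergence is declared when the Pearson correlation ("fidelity") between
the model-reproduced and observed off-diagonal correlations reaches 0.99.

Design choices that were genuinely open, and how they were resolved:

* **Metropolis kernel.** Angle proposals $\theta' = \theta + U(-w, w)$,
  with $w$ tuned toward ~50 % acceptance during burn-in (factor-1.15
  adjustments every 50 sweeps). Burn-in is $100N$ sweeps from a random
  start; retained samples are separated by 10 thinning sweeps in the
  samplers (5 inside the learning loop, where slight sample correlation is
  harmless because the update only needs an unbiased gradient direction).
  The sampler uses its own platform-stable RNG so identical seeds give
  bit-identical results everywhere.
* **Learning schedule.** The published description of the original learning
  schedule is not available in detail, so the schedule is the package's own:
  $\eta_J = 0.3$ decaying geometrically by 0.997 per iteration,
  $\eta_h = 0.1$, Monte Carlo sample size starting at 1500 and growing by
  2 % per iteration (capped at 20 000), at most 500 iterations. A smaller
  $\eta_J = 0.1$ also converges but needs roughly four times as many
  iterations at $N = 25$, while $\eta_J \ge 0.5$ can overshoot into the
  frozen phase on unlucky seeds (connected correlations collapse there, so
  the mismatch keeps pushing the couplings up — a runaway the divergence
  guard reports). The moment-matching fixed point is the same for any
  stable rate, and tests verify fidelity $\ge 0.99$ plus recovery of
  planted couplings at $r \ge 0.9$.
* **Missing pairs.** Pairs dropped upstream (too few jointly valid samples)
  are excluded from the update; their couplings stay frozen at 0.
* **Regularisation.** None by default; optional L2 shrinkage on $J$ behind
  the `lambda` argument for ill-conditioned targets.
* **Divergence.** A persistent fall of fidelity far below its running best
  raises an error carrying the full fidelity trace.

## Thermodynamics: heat capacity and the critical temperature

With the fitted model in hand, `scan_temperatures()` asks the counterfactual
question: what would the ensemble look like if the interactions were
effectively stronger or weaker than observed? Temperature scales exactly
inversely to a global coupling scale (the Boltzmann weights depend only on
$J/T$), so sweeping $T$ with $J$ fixed is the cleanest implementation.
At each grid temperature the heat capacity is computed from the
energy-fluctuation identity

$$C_V(T) = \frac{\langle E^2\rangle_{P_T} - \langle E\rangle_{P_T}^2}{T^2},$$

which equals $\partial\langle E\rangle/\partial T$; the tests verify the two
routes agree within Monte Carlo error. The critical temperature $T_c$ is the
peak of $C_V(T)$ on a default grid of 22 evenly spaced temperatures on
$[0.17, 1.43]$ (endpoints are the stated sweep range; the point count is a
package choice, configurable). Because the raw argmax is brittle under
Monte Carlo noise, the peak is located by a local quadratic fit around the
argmax of a 3-point moving average; a curve whose total variation does not
exceed the noise floor is reported as `T_c = NA` with a diagnostic, which is
the expected outcome for uncoupled (null) data. $T_c < T_o = 1$ places the
observed system on the disordered ("liquid") side; $T_c$ near 1 means the
audience was operating near criticality, where groups of similar viewing
behaviour emerge while diversity between groups survives.

`tc_from_eigenvalue()` provides the mean-field shortcut
$T_c \approx \lambda_{\max}(J)/2$ (the factor $1/2$ is the two-component
vector-model mean-field constant; the derivation for this choice was not
available, so the mean-field value is used and recorded). The estimate is
biased relative to the Monte Carlo $T_c$ but strongly correlated with it,
which is exactly how it should be used.

**A subtlety about the susceptibility.** In the rotation-symmetric model
($h = 0$) the time-averaged mean direction vanishes, so the plain average
connected correlation is *monotone* in temperature, not peaked. The correct
finite-size expression of "susceptibility is maximal at criticality" is the
fluctuation-dissipation link: with $h = 0$ the energy is (minus) the
coupling-weighted sum of pair correlations, so $C_V \propto$ the *rate of
change* of the average correlation, which is steepest at the $C_V$ peak.
The test suite checks that identity; the commonly quoted
peak-coincidence of the $|m|$-based susceptibility holds only up to $O(1/N)$
pseudo-critical shifts, which are sizeable at $N \le 25$.

## Networks, modularity, homophily

The viewer network thresholds the couplings: $A_{ij} = 1$ iff
$J_{ij} > J_o$, with $J_o$ chosen per video at the emergence of the giant
component — the first candidate threshold (scanning the sorted unique
couplings from strongest to weakest) at which the largest connected
component spans more than half the nodes. Majority spanning is the standard
percolation surrogate; the fraction is configurable. Negative couplings are
naturally excluded for $J_o \ge 0$; no signed-modularity variant is used.

Modularity uses the standard normalisation

$$Q = \frac{1}{2m}\sum_{ij}\left(A_{ij} - \frac{a_i a_j}{2m}\right)
\delta(c_i, c_j),$$

with $m$ the edge count. A literal alternative reading of the defining
formula (prefactor $1/(4m)$) exists in the source material; it is available
behind `modularity_q(..., literal = TRUE)` but is not the default, because
only the standard normalisation reproduces the accepted closed forms (two
equal disconnected cliques give $Q = 1/2$; a single community gives
$Q = 0$). Community labels come from igraph's multi-level (Louvain)
maximisation; an exhaustive set-partition search (`method = "exact"`) is
available for $\le 12$ nodes as a test oracle.

One caveat for null comparisons: optimised modularity of a sparse *random*
graph is substantially positive by chance (≈ 0.4 at 10–16 nodes), so
"no community structure" cannot be read off the absolute $Q$ of a
randomisation control. The tests therefore measure structure destruction as
the loss of alignment between the thresholded network and the planted
communities, which does collapse to zero under shuffling while the
structured pipeline retains it.

Rating homophily is

$$O = \frac{1}{N(N-1)}\sum_{i}\sum_{j\neq i}
\left(1 - \frac{|p_i - p_j|}{p_{max}}\right),$$

with $p_i \in [0, p_{max}]$, $p_{max} = 10$: 1 for perfect agreement,
$(N-2)/(2(N-1)) \to 1/2$ for the worst-case even split between the scale
extremes. The double sum over ordered pairs is implemented literally.

## Preprocessing chain

Raw gaze panels pass through, in order:

1. **Zero-phase triangular low-pass filter**, total width 80 ms (21 taps at
   250 Hz), unit-sum kernel; every sample within half a window (40 ms) of a
   missing sample becomes missing, which reproduces the implicit mask
   expansion of zero-phase filtering over gaps. Edge samples use a
   renormalised partial kernel.
2. **Subject exclusion**: strictly more than 20 % missing in a video
   removes the subject for that video.
3. **Outlier and gap interpolation**: per-subject outliers are flagged at
   5 MADs from the coordinate median (the original artifact criterion is
   not stated; a robust scale rule is the conventional choice), then
   missing/outlier samples are filled by an EM-style truncated-SVD low-rank
   reconstruction across subjects (default rank 1) — a stand-in for the
   original sparse-PCA step, justified by its own description as
   effectively interpolating from the other viewers. Observed samples are
   never altered, and the original missing mask is *retained*: by default
   all correlation averages exclude originally-missing samples
   (pairwise-complete), because the alternative 0-filling convention
   distorts means; 0-filled behaviour remains available by ignoring the
   mask (`to_directions(..., use_missing_mask = FALSE)` after filling).
4. **Segmentation** into non-overlapping 30-s increments (half-open sample
   windows); a trailing remainder is dropped, and videos shorter than one
   segment are rejected — analysis and inference run per increment and
   per-video quantities are segment averages.
5. **Direction extraction** by central differences; samples with speed
   below $10^{-9}$ px/sample (fixations) or a missing stencil are marked
   invalid rather than given an arbitrary direction.

## The synthetic generator: what it emulates, what it does not

`simulate_video()` draws direction series from the Boltzmann distribution of
a *planted* XY model (balanced groups, `within_coupling` = 0.5,
`between_coupling` = 0.05 by default, temperature 1), integrates them into
pixel trajectories with a constant-speed profile (30 px/sample with 20 %
multiplicative jitter) reflected at the borders of a 1440 × 2560 screen,
injects burst-structured dropout (geometric bursts, mean 100 ms, total rate
2 % by default), and assigns group-mean ratings with Gaussian noise clipped
to $[0, 10]$. Defaults mirror the stated recording conditions (25 subjects,
30-s segments at 250 Hz) where conditions are stated; the speed profile,
dropout geometry and rating noise are generator choices a practitioner
would call realistic, fixed once and not revisited. Known departures from
real data: gaze speed is not empirically calibrated (only directions enter
the analysis); there is no video content driving coordinated saccades (the
planted couplings induce alignment directly); and stored direction samples
are thinned Monte Carlo draws (10 sweeps apart, approximately independent),
whereas real gaze directions are autocorrelated on the saccade timescale.
The thinning matters: with unthinned (heavily autocorrelated) chains, the
window mean of a strongly coupled ensemble soaks up the slowly diffusing
common orientation and the finite-window *connected* correlation becomes
erratically small — a symmetry artifact of the drive-free generator, not a
feature of content-driven gaze, which reorients many times per segment. A
green end-to-end test therefore establishes that the pipeline recovers
planted interaction structure, critical temperatures and communities from
data obeying its own model assumptions — not that real recordings obey
those assumptions.

## Numerical choices and degenerate inputs

* Unit-vector validity tolerance $10^{-9}$; energies reject non-unit states.
* Correlation pairs need at least 100 jointly valid samples by default;
  failing pairs are `NA`, excluded from $C_\sigma$ and frozen during
  fitting.
* `percolation_threshold()` places $J_o$ halfway between the admitting
  coupling and the next weaker one (so thresholding at $J_o$ reproduces the
  spanning graph); all-equal couplings are degenerate and returned with a
  warning.
* Edgeless graphs have undefined modularity (error); networks with no
  super-threshold edge report `Q = NA`.
* Flat heat-capacity curves give `T_c = NA` ("undefined") rather than a
  spurious grid argmax.
* All stochastic stages take explicit integer seeds; the compiled sampler's
  RNG is platform-stable, so every result is bit-reproducible.

## Limitations

* Boltzmann learning needs $O(10^2)$ Monte Carlo iterations per segment;
  the default budgets are sized for $N \approx 25$ viewers.
* The percolation rule and the $T_c$ peak both operate on finite grids;
  both report their resolution rather than pretending to continuum
  precision.
* No EDF/ASC parsing, no saccade event detection, no saliency modelling,
  no signed or weighted modularity, and no finite-size-scaling
  extrapolation of $T_c$ — the analysis works at fixed $N$ with the peak
  definition.
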