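# gazetherm

Thermodynamic analysis of collective gaze behaviour.

When a group of viewers watches the same video, their eye movements partly
synchronise. `gazetherm` quantifies that collective behaviour for
researchers in visual attention, media research and collective-behaviour
physics: it computes inter-subject correlations of gaze position and
eye-movement direction, infers pairwise viewer "interactions" by fitting a
maximum-entropy model, locates the ensemble's critical temperature from
heat-capacity curves, and characterises the community structure of the
interaction network, together with rating-homophily statistics.

## The model in brief

Eye-movement directions are unit 2-vectors
σᵢ(t) = vᵢ(t)/|vᵢ(t)|, with vᵢ(t) = ½(rᵢ(t+1) − rᵢ(t−1)). Their observed
means μᵢ and connected correlations

C_ij = ⟨σᵢ(t)·σⱼ(t)⟩_t − μᵢ·μⱼ

are matched by the maximum-entropy distribution, which is the Boltzmann
distribution of a fully connected XY model at operating temperature T_o = 1:

E(σ) = −Σᵢ hᵢ·σᵢ − Σ_{i<j} J_ij σᵢ·σⱼ,  P_T(σ) ∝ exp(−E(σ)/T).

Couplings J_ij are inferred by Monte Carlo Boltzmann learning
(moment-matching updates with Metropolis sampling). Scanning temperature
and locating the peak of the heat capacity
C_V(T) = (⟨E²⟩ − ⟨E⟩²)/T² yields the critical temperature T_c: values near
1 mean the audience viewed the material near a collective ordering
transition. Thresholding J at the giant-component percolation point gives a
viewer network whose modularity Q measures how distinctly the audience
splits into groups with shared viewing patterns. Rating homophily
O = 1 − mean pairwise |pᵢ − pⱼ|/p_max summarises agreement of preference
ratings.

A synthetic-data generator (planted XY couplings with community structure,
burst dropout, homophilous ratings) makes the whole pipeline testable
without external eye-tracking data.

## Worked example

```r
library(gazetherm)

# a synthetic 30-s "video": 10 viewers in 2 planted groups
cfg <- synthetic_config(n_subjects = 10, within_coupling = 0.5,
                        between_coupling = 0.08, sample_rate_hz = 50)
v <- simulate_video(cfg, seed = 1)

res <- run_video(v$panel, ratings = v$ratings$rating,
                 config = run_config(fit_samples = 1000, max_iter = 150,
                                     t_points = 12, scan_samples = 1000),
                 video = "demo")
res$summary[, c("C_sigma", "T_c", "T_c_eigen", "Q", "homophily")]
#>     C_sigma       T_c T_c_eigen        Q homophily
#> 1 0.4221145 0.8347517  1.272107 0.452381 0.7402908
```

Reading the numbers: `C_sigma` ≈ 0.42 is the average pairwise connected
direction correlation (the susceptibility) — strongly synchronised viewing.
`T_c` ≈ 0.83 < 1 places the ensemble on the disordered ("liquid") side of
the transition but near criticality; `T_c_eigen` is the fast mean-field
estimate λ_max(J)/2, biased upward but strongly correlated with the Monte
Carlo value. `Q` ≈ 0.45 says the inferred interaction network splits into
well-separated communities (the two planted groups), and homophily ≈ 0.74
reflects the planted two-group rating structure. A randomisation control
(`null_pipeline_check()`) on shuffled trajectories collapses all of these:
C_sigma near 0, couplings near 0, T_c at the grid minimum or undefined,
and no meaningful modularity.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance targets from
scratch — the closed-form bounds of the rating-homophily statistic,
evaluated through the package's own `homophily()` on constructed rating
vectors — and writes them as JSON, while also running one synthetic
fit-and-scan as a pipeline check:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
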