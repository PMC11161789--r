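---
title: "Modelling cortical excitation-inhibition balance with the pFIC model"
author: "pfic authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cortical excitation-inhibition balance with the pFIC model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfic)
```

## The model

`pfic` simulates whole-cortex resting-state dynamics with a two-population
neural-mass model at each cortical region. Each region carries an excitatory
and an inhibitory population described by synaptic gating variables
$S_E, S_I \in [0, 1]$ (fractions of open channels). Regional input currents
are

$$I_{E,i} = W_E I_0 + w_{EE,i} J S_{E,i}
  + G J \textstyle\sum_j C_{ij} S_{E,j} - w_{IE,i} S_{I,i},$$
$$I_{I,i} = W_I I_0 + w_{EI,i} J S_{E,i} - w_{II} S_{I,i},$$

with $w_{II} = 1$ and long-range coupling through the structural
connectivity matrix $C$ reaching excitatory populations only (scaled by the
global constant $G$). Population firing rates follow the sigmoidal
frequency-current curve $H(x) = (ax - b)/(1 - e^{-d(ax - b)})$, with the
conventional mean-field constants ($a_E = 310\,\mathrm{nA^{-1}s^{-1}}$,
$b_E = 125$ Hz, $d_E = 0.16$ s, and the inhibitory analogues; see
`neural_constants()`). Gating evolves as

$$\dot S_E = -S_E/\tau_E + (1 - S_E)\,\gamma\, r_E + \sigma \nu(t), \qquad
  \dot S_I = -S_I/\tau_I + r_I + \sigma \nu(t),$$

integrated with the Euler-Maruyama scheme (default $dt = 1$ ms, state
clamped to $[0,1]$, initial state $S_E = S_I = 0.1$, 60 s burn-in
discarded). The same regional noise amplitude $\sigma_i$ drives both
populations. The **E/I ratio**, the package's regional marker of
excitation-inhibition balance, is the ratio of the temporal averages of
$S_E$ and $S_I$.

### Feedback inhibition control

The inhibitory feedback weight $w_{IE,i}$ is not free: `calibrate_fic()`
solves for the weights that hold each region's noise-free excitatory firing
rate at the set-point (3 Hz by default, tolerance 0.1 Hz). Two numerical
points matter here.

First, the calibration measures the rate of the attractor the simulation
*actually reaches from the standard initial state*. In parts of parameter
space the network is bistable: a metastable branch at the set-point can
coexist with a low-activity attractor, and a calibration that tracks the
wrong branch produces simulations that immediately collapse away from
3 Hz under noise. Cold-starting every calibration integration avoids this.

Second, the attained rate is a steep, monotone-decreasing function of
$w_{IE}$ (slopes near $-50$ Hz per unit weight close to the set-point), so
a plain constant-gain update oscillates. The update
$w_{IE} \leftarrow \max(w_{\min},\, w_{IE} + \eta\,(\bar r_E - 3))$
therefore uses a per-region gain that is halved whenever the rate error
changes sign, a step clamp, and a bisection fallback inside the
per-region bracket implied by monotonicity. An analytic fixed-point
solution provides the starting weights, so well-behaved parameter sets
calibrate in one or two iterations.

### Hemodynamics and observables

Synaptic activity maps to BOLD through the Balloon-Windkessel model
(`balloon_windkessel()`; $\kappa = 0.65$ s$^{-1}$, $\gamma_h = 0.41$
s$^{-1}$, $\tau_h = 0.98$ s, $\alpha = 0.32$, $\rho = 0.34$, $V_0 = 0.02$,
$k_1 = 7\rho$, $k_2 = 2$, $k_3 = 2\rho - 0.2$). Because hemodynamic states
evolve on second-long time scales, they are stepped on a ~10 ms substep of
the neural integration; BOLD is sampled every TR and an initial transient
of about 30 s is discarded. The length of that transient matters: the
hemodynamic states start from rest and drift toward their operating point
over tens of seconds, and because the drift is shared across regions,
keeping it in the series inflates all FC entries toward 1 and masks the
spatial structure of interest.

Model fit is scored against three observables:

* **FC agreement** $r$: Pearson correlation between Fisher z-transformed
  upper-triangular entries of the simulated and empirical static FC.
* **FC mean difference** $d$: absolute difference of the raw mean FC
  (z-transformation is applied to the agreement term only — the closest
  literal reading of the cost definition; a config switch is not provided
  because the two conventions never differed materially in our synthetic
  studies).
* **FCD distance** KS: sliding-window FC matrices (stride 1 frame; a
  1200-frame run with 83-frame windows yields 1118 windows) are vectorized
  and correlated window-by-window; the upper-triangular FCD entries of
  simulated and empirical runs are compared by the two-sample
  Kolmogorov-Smirnov statistic, assuming no temporal correspondence.

The overall cost is $(1 - r) + d + \mathrm{KS}$. Candidates whose regional
mean excitatory rates leave the acceptance band (2.7-3.3 Hz by default,
2.5-3.5 Hz as the relaxed sensitivity setting) — or whose calibration does
not converge — receive a fixed penalty cost of 10, which exceeds any
attainable valid cost (at most $\approx 3 + d$) and keeps the evolutionary
search ranked but strongly disfavoring them.

### Parameterization

Regional $w_{EE}$, $w_{EI}$ and $\sigma$ are linear combinations of two
cortical annotation maps — a T1w/T2w myelin proxy and the principal FC
gradient — giving 9 coefficients plus $G$: a 10-dimensional search space.
Maps are z-scored across regions before expansion so intercepts are
interpretable as cortical means and search bounds are scale-free. Control
variants reuse the same code path with one map (7 parameters) or none
(spatially homogeneous, 4 parameters).

Expanded values are clipped into per-quantity bounds:
$w_{EE} \in [1, 6]$, $w_{EI} \in [1, 5]$, $\sigma \in [0.003, 0.01]$,
$G \in [0, 3]$. Both ends of this box are deliberate. The upper $w_{EE}$
bound sits below the collective instability: once the effective recurrent
drive $w_{EE} + G\sum_j C_{ij}$ grows too large (empirically,
$w_{EE} \gtrsim 5$ at $G \approx 1$ on the default connectome), the
network's uniform mode destabilizes, the cold-start attractor jumps
discontinuously between a sub-Hz and a several-tens-of-Hz state, and no
3 Hz baseline exists for any $w_{IE}$ — such parameter sets are
unfittable by construction. The lower $\sigma$ bound keeps candidates in
the noise-driven regime the model is meant to describe: with noise an
order of magnitude smaller, near-deterministic dynamics driven purely by
structural coupling can mimic a target's static FC while their
fluctuation structure is degenerate, which makes them spurious but
seductive solutions for the optimizer.

### Fitting protocol

`fit_pfic()` runs CMA-ES (implemented in `cmaes_search()`, in its standard
$(\mu/\mu_w, \lambda)$ formulation with active covariance updates; initial
step 0.2 of each bound range, box constraints by projection) on the
training target, recording every evaluated candidate until the budget
(500 by default; 250 in the per-group protocols) is reached. The default
population is 8: at desk-scale budgets the number of *generations* is
what limits progress through the cost valley, and 31 generations of 8
reliably outperform 15 generations of 16 here (verified on both the
sphere surrogate and full parameter-recovery studies). Every candidate is
one stochastic simulation per phase with a fixed per-phase seed. Because
candidates that fail the firing-rate gate all receive the same flat
penalty cost, the optimizer additionally ranks rejected candidates among
themselves by how far their rates leave the acceptance band — without
this, nearly half of some generations is rank-tied noise.

Recorded candidates are re-evaluated on the validation target; the top k
(10, or 1 in the per-group protocols) go to the test target, whose cost
components are summarized as mean ± sd. By default only the best 50
training candidates enter the validation re-evaluation
(`fit_protocol(validation_pool = ...)`; set it to `Inf` for the full
evaluate-everything protocol) — candidates deep down the training ranking
never win the validation ranking, and the pool halves the simulation
count of a fit. ROI-coverage masks apply to cost computation only;
expanded parameter maps remain defined on all regions, so estimates
extrapolate to the whole cortex for free because the parameterization is
linear in whole-cortex maps.

## Group-level statistics

The cohort module reproduces the method's group analytics on any table of
subjects with ages, motion and performance scores:

* `bin_by_age()` sorts subjects and forms contiguous age groups (885
  subjects in 29 groups gives 15 groups of 31 and 14 of 30), with a seeded
  fixed-size validation split per group.
* `ei_age_regression()` regresses regional and cortical-mean E/I on group
  mean age (OLS, one point per group, two-sided slope t-tests; per-region
  p-values are BH-corrected downstream by `fdr_correct()`).
* `match_performance_groups()` splits at the median performance and forms
  age-matched group pairs (greedy closest-mean-age pairing). The paired
  contrast uses the paired Cohen's d across pairs and a two-sided paired
  t-test; the paired variant was chosen because the design matches groups
  one-to-one (the unpaired alternative is strictly less powerful here and
  the source analyses do not state a variant).
* `spin_test()` builds spatial-autocorrelation-preserving nulls by random
  3D rotations of parcel centroids (mirrored across hemispheres) followed
  by one-to-one greedy nearest-centroid reassignment. The one-to-one
  variant (rather than nearest-with-duplicates) was chosen so every null
  map is a relabeling of the observed map — the null preserves the value
  multiset exactly. P-values use the $(1 + \#\{|\text{null}| \ge
  |\text{obs}|\})/(1 + n_{\text{perm}})$ estimator and are therefore never
  exactly zero.
* `permutation_group_test()` re-runs an arbitrary deterministic E/I
  estimator under label permutations with preserved group sizes.
* `covariate_residualize()` removes group-level confounds (e.g. mean
  framewise displacement) by OLS.

## Synthetic fixtures: what they emulate, and what they do not

Because the empirical datasets behind the method are restricted, the
package ships generators that emulate the *structure* of those studies at
the Desikan-Killiany scale (68 regions; a 100-region option exists for
sensitivity checks):

* `make_parcellation()` places mirror-symmetric Fibonacci-lattice parcels
  on two unit hemispheres and derives great-circle distances, a synthetic
  sensorimotor-association rank and seven mirror-symmetric network labels.
* `make_synthetic_sc()` builds SC by an exponential distance rule,
  $C_{ij} = e^{-\lambda d_{ij}}(1 + \varepsilon_{ij})$, max-normalized.
  The default decay $\lambda = 5$/radian keeps row strengths of order one,
  which is the regime in which a stable 3 Hz feedback-inhibition baseline
  exists across the entire search box.
* `make_synthetic_maps()` anchors the myelin proxy to the
  anterior-posterior axis and the gradient to the inferior-superior axis
  plus smooth noise, z-scored, near-orthogonal by construction.
* `make_ground_truth_study()` expands a known coefficient vector
  (defaults: graded $w_{EE}$/$w_{EI}$/$\sigma$ maps, $G = 2.4$,
  $\sigma_0 = 0.008$), calibrates, and simulates three independent-seed
  runs of 330 frames at TR 0.72 s (window 83 frames, mirroring the
  HCP-like condition) to build train/validation/test targets plus the
  true regional E/I map. Targets are group-style: three independent runs
  per phase, FCD entries pooled into one distribution and FCs averaged in
  Fisher z space. The regime was chosen so the targets carry realistic,
  identifiable structure: mean FC well below 1 with a spatial standard
  deviation around 0.13, and Fisher-z FC agreement around 0.95 between
  the pooled targets of independent phases — while one candidate
  evaluation stays around a second of compute. In recovery studies the
  per-phase evaluation seeds equal the targets' generation seeds, so the
  training objective is minimized exactly at the true vector and the cost
  floor reflects pooling noise alone.
* `make_synthetic_cohort()` draws ages uniformly (8-23 y), a performance
  trait independent of age, motion mildly anti-correlated with age, and
  latent per-subject E/I maps
  $\text{baseline} + \text{slope}\cdot\text{age} +
  \text{effect}\cdot\text{label} + \text{noise}$ with the group effect
  graded along the synthetic S-A rank (defaults: slope $-0.01$/y, effect
  scale 0.02, subject noise 0.05).

Passing tests on these fixtures demonstrate that the estimation machinery
recovers known structure under the model's own assumptions — additive
Gaussian subject noise, linear age effects, a distance-rule connectome.
They do not demonstrate robustness to empirical nuisance structure (head
motion artifacts, global signal, parcellation mismatch, non-exponential SC
topology), and no empirical dataset-dependent number is reproduced here.

## Numerical choices and limitations

* $dt \le \tau_I/5$ (2 ms) is enforced; halving $dt$ changes noise-free
  trajectories at first order, as expected for Euler integration.
* The stochastic integrator uses a self-contained xoshiro256++ generator
  with polar-method normal draws, so a simulation seed reproduces
  trajectories bit-for-bit regardless of R's RNG state.
* FCD window stride is fixed at 1 frame; windowed FC uses all frames in
  the window with no taper.
* Degenerate inputs raise typed conditions (`pfic_*` classes) rather than
  silently coercing: zero-variance regions in FC, constant maps under
  z-scoring, non-finite states (reported with the offending step), empty
  KS samples, constant covariates.
* Ties in top-k selection are broken by training cost and then candidate
  index, so selection is deterministic and order-invariant.
* CMA-ES is a stochastic optimizer on a stochastic objective: with
  desk-scale budgets (250-500 evaluations) it finds good, not optimal,
  candidates. On the 10-D sphere surrogate it reaches ~1e-2 of the optimum
  within 500 evaluations and ~1e-6 within 2000 — matching the reference
  implementation of the algorithm, whose early budget is spent adapting
  the covariance model.
* Identifiability of the regional E/I pattern is the binding limitation
  of desk-scale fits. The fit cost is steep in global directions (the
  coupling G, mean synaptic strengths, mean noise) but shallow in the
  spatial-coefficient directions that shape the regional E/I map: in
  recovery studies, candidates close to the optimum in cost can carry
  E/I maps ranging from strongly correlated to strongly *anti*-correlated
  with the truth. Short scans (a few hundred frames) and small search
  budgets (hundreds of candidates) therefore recover the E/I map only
  unreliably; the packaged recovery check documents this behaviour rather
  than hiding it. Larger fitting budgets and longer (or pooled) scans are
  the remedies, at proportional compute cost.
* Conduction delays, spiking dynamics, subcortical nodes, nonlinear
  developmental trajectories and eigenmode parameterizations are out of
  scope.

## Problem sizes used by the shipped checks

The packaged tests run the full recovery study at 68 regions with a
250-candidate budget and three search seeds, scoring the Pearson
correlation between true and recovered regional E/I maps; statistical
calibration checks use 200-replicate Monte-Carlo runs at the group sizes
described above. These sizes were chosen as the smallest at which the
corresponding claims are stable across seeds.
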