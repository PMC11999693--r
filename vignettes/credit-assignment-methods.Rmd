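---
title: "Models and methods for contingent-learning credit assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for contingent-learning credit assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creditlearn)
```

This vignette documents the models behind `creditlearn`, the choices made
where the design was genuinely open, and what the synthetic-data analyses
do and do not establish about real data.

## The task and its causal structure

On every trial the participant chooses between two shapes, S1 and S2. Each
shape leads to outcome identity O1 with its own slowly drifting probability
(`p1`, `p2`, independent across shapes) and to O2 otherwise. The points
attached to each identity change randomly every trial (integers 20–100,
difference at least 15), so only the *identity* contingencies are worth
learning. In **direct** blocks the outcome of trial *t*'s choice is shown
on trial *t*; in **indirect** blocks the outcome shown on trial *t* was
caused by the choice on trial *t − 1*, and the first display of a block is
causally unlinked. The trial table records this linkage explicitly in
`causal_choice_trial`, and every downstream computation (belief updates,
lag regressors, pattern labels) uses it.

Candidate schedules are accepted only if an ideal Bayesian learner
(α = 1, greedy argmax with random ties) chooses S1 on 42–57% of trials.
This is a hard rejection filter: it keeps classes near-balanced for the
decoding analyses and removes degenerate schedules in which one shape
dominates.

### Choices where the design was open

* **Drift process.** The generative process of `p1`, `p2` is rarely reported
  beyond example trajectories; we chose a Gaussian random walk
  on the log-odds scale (step sd 0.15 per trial) clipped to \[0.1, 0.9\].
  A walk on log-odds keeps steps scale-appropriate near the bounds; the sd
  gives trajectories that traverse most of the allowed range over ~150
  trials without being unlearnable.
* **Magnitude constraint.** The printed constraint is a property (lag-1
  autocorrelation below 0.2), not a mechanism; we enforce it by
  whole-sequence rejection sampling, separately per outcome identity.
* **Template repetitions.** 12 presentations per stimulus per template
  block (a free design parameter); enough trials to train the
  identity decoders with two classes per fold.
* **Acceptance budget.** 500 candidate schedules; in practice acceptance
  occurs within a handful of attempts.

## The Bayesian volatility learner

For each shape the learner maintains a joint density over

* `p` — the probability the shape leads to O1 (grid: 50 midpoints of (0,1)),
* `v` — log-volatility; larger `v` means the contingency is believed to
  change faster (grid: 30 uniform points in \[−8, 2\]),
* `k` — the variance of the random walk on `v` (grid: 14 log-spaced points
  in \[e^−5, e^0.5\]).

One update step per displayed outcome: diffuse `v` with a Gaussian kernel
of variance `k`; diffuse `p` with a beta kernel centered on the previous
`p` with concentration `s = exp(−v_t)`; multiply by the Bernoulli
likelihood of the observed identity; renormalize. The reported belief `p̂`
is the mean of the `p` marginal. Numerical notes: kernels are precomputed
row-stochastic matrices, so every update is a small set of matrix products
and mass is conserved to 1e−10 per trial (asserted in tests); a
`freeze_dynamics` switch disables both diffusions, which reduces the
learner to a conjugate Beta–Bernoulli estimator and provides an exact
oracle (the grid posterior mean matches the conjugate mean to ~1e−4 with
the default grid).

Open points resolved as follows: the mapping from a (mean, variance)
description of the beta transition kernel to shape parameters is not
determined, so we use `Beta(μs, (1−μ)s)` with `s = exp(−v)` — monotone in
`v` and always a proper density; the *unchosen* (non-causal) shape receives
the diffusion (prediction) step but no likelihood each trial, because
contingencies drift in real time whether or not they are sampled; the
expected value uses the multiplicative α convention as printed
(`p̂·m_O1·α + (1−p̂)·m_O2/α`), with the exponent reading available via
`alpha_mode = "exponent"`.

The RL alternative caches one value per shape, updated only for the causal
shape with the α-weighted points of the obtained outcome (α for O1, 1/α
for O2, so α plays the same role in both models); the softmax uses `b`
directly on cached values.

## Parameter fitting

`fit_learner()` maximizes the choice likelihood with a random-walk
Metropolis chain: 4,000 iterations, 500 burn-in, Gaussian proposals with
sd = 5% of each parameter's range, reflected at the bounds (α ∈ (0,2),
b ∈ (0,1), δ ∈ (0,1)), initialized at α = 1, b = 0.5, δ = 0.5. The point
estimate is the maximum-likelihood sample, matching the
likelihood-maximization target; the chain is kept for diagnostics only.
Because the belief trajectory of the Bayesian learner depends only on the
observed choice–outcome stream and not on (α, b), it is propagated once
per dataset and each likelihood evaluation is a vectorized softmax — this
is what makes MCMC with grid-integration beliefs cheap. Recovery at the
study's scale (148 trials) gives mean absolute errors of roughly 0.03 for
α and 0.07 for b at generating values (1.2, 0.3) (recomputed by
`scripts/acceptance.R` and the test suite).

## Lagged credit regression

Eligible trials (complete 3-back history within a run × condition block;
indirect rows whose outcome lags touch the unlinked first display are
excluded) contribute nine regressors `C_{t−i}O_{t−j}`: +1 when the lagged
choice, had it been repeated, would have produced the *currently desired*
outcome (the identity with the larger current point value), −1 otherwise.
The per-run logistic fit uses IRLS with an L2 penalty (λ = 1) on the
slopes only. The penalty is a deliberate deviation from a plain logistic
fit: with 37-trial blocks, rule-consistent behavior frequently separates
perfectly, and an absolute λ = 1 stabilizes the fit while keeping
coefficients near the unpenalized scale (the λ → 0 limit is checked
against `stats::glm` in the tests). Appropriate cells are the diagonal
(direct) or `choice lag = outcome lag + 1` (indirect); contrasts are
one-tailed paired t tests, matching the directional hypotheses. Precision
is the Pearson correlation of the nine coefficients with the binary ideal
matrix, averaged over conditions.

## The synthetic neural cohort

The generator emulates, at the trial-beta level, exactly the statistical
structure the neural analyses assume: causal-choice prototypes (unit-norm
Gaussian vectors per ROI × label × phase family) at feedback in lOFC/HC;
pending-choice prototypes at interim feedback in lFPC with amplitude
`A(1 + 0.5 tanh f_t)`, `f_t ~ N(0,1)`; the matching credit-assignment
pattern one display later with amplitude driven by
`g_t = ρ f_t + √(1−ρ²) ε_t`; template identity codes shared between
template and feedback phases in HC only (blend weight `share`); i.i.d.
Gaussian voxel noise everywhere.

Defaults: 20 subjects, amplitude A = 3, noise sd 1, ρ = 0.6, share = 1 on
a 24×24×16 volume with 6×6×6 ROIs. A = 3 puts searchlight accuracies in
the 0.8–0.9 range — strong but below ceiling, so distance-based analyses
retain variance. Two regimes matter for interpretation:

* The **fidelity-coupling recovery band**: with A = 8 (high-fidelity
  regime) the recovered seed→target correlation lands within
  \[0.4ρ, ρ\]; at A = 3 pattern noise attenuates it further (roughly
  0.15ρ–0.3ρ). Monotonicity in ρ holds in both regimes.
* The **conditional-accuracy control** is a sign-level effect and is
  intrinsically small under this generator (~0.005 at its optimum near
  A = 3): amplitude must vary enough to flip correctness, yet accuracy
  must stay off ceiling. The tests therefore use a paired design (two
  cohorts sharing their noise stream, differing only in ρ).

What passing these analyses does *not* show about real data: patterns here
have no hemodynamics, no temporal autocorrelation, no motion or
physiological structure, no anatomical geometry, and prototypes are
orthogonal in expectation. The synthetic cohort validates the *pipeline*
(labels, linkage, cross-validation, null construction, inference), not
effect sizes in real fMRI.

## Decoding and group inference

Searchlights are 5×5×5 cubes around every in-mask centroid with at least
10 valid surrounding voxels. Each trial's values are z-scored across the
searchlight's voxels, classified with a linear soft-margin SVM (cost 1;
dual coordinate descent with an augmented bias feature, cross-checked
against libsvm in the tests), cross-validated run-wise, and compared to a
voxel-specific null built from 100 training-label shuffles; maps report
accuracy minus the null mean. Signed distances divide the decision value
by the weight norm and take the sign of correctness.

Information connectivity correlates the seed region's interim-feedback
distance series with each target searchlight's next-feedback distance
series for the same causal choice, Fisher-z transformed (r clipped at
1 − 1e−7). One analysis choice deserves emphasis: both series are centered
within CV fold × class before correlating. With two runs, fold-level
fidelity differences and training-class imbalance move *both* regions'
signed distances in the same direction, which would otherwise produce a
positive correlation even when the generator's coupling is zero; centering
restores a clean null (group-mean z ≈ 0 at ρ = 0) while leaving the
trial-level coupling effect intact.

Group inference: maps may be smoothed with a separable reflective Gaussian
kernel (default FWHM 2 voxels on the synthetic geometry; this plays the
role an 8 mm kernel plays on real acquisitions); per-voxel one-sample t
(df = n − 1); TFCE with H = 2, E = 0.5, dh = max/100, 6-connectivity
(step and connectivity are rarely reported alongside the default H and E; the
compiled implementation is verified against a brute-force threshold-sum
oracle); family-wise correction by sign-flip permutation of subject maps
with the max-TFCE null within the ROI mask, p = (1 + #{null ≥ obs}) /
(n_perm + 1). The default desk-scale permutation count is 500 with the
conventional 5,000 available by argument. The precision↔decoding
association converts the across-subject correlation to t and applies the
same TFCE machinery with score permutation.

## Problem sizes used by the test and acceptance runs

Tests and the acceptance script run the full method at reduced scale,
chosen as the smallest sizes at which each property is statistically
decisive: a 12×12×8 volume with 4×4×4 ROIs (14×14×10 where searchlight
edge-clipping matters), 20-subject cohorts, 100-permutation decoding
nulls, 199-permutation TFCE with 10-subject null cohorts (200 replicates
for the family-wise error rate), and a coarse 20×8×5 belief grid wherever
grid resolution is not itself under test. The full-scale defaults
(24×24×16 volume, 50×30×14 grid, 5,000 permutations) are a flag away.

## Known limitations

* Belief updating is first-order Markov on a fixed grid; very low `v`
  regions are limited by grid resolution.
* The MCMC fitter reports a maximum-likelihood point, not a posterior; no
  convergence diagnostics beyond the acceptance rate are computed.
* The credit regression pools no information across participants
  (no mixed-effects pooling) and omits magnitude-history regressors.
* Indirect-block outcome lags are indexed by display trial, one of two
  defensible readings of the lag notation.
* The searchlight is plain and exhaustive; no spatial shortcuts beyond
  vectorization are attempted.
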