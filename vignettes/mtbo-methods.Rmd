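---
title: "Models and methods behind mtbo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtbo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models, the numerical choices and
the deliberate design decisions in `mtbo`, in the spirit of a methods
section: what is assumed, what is tunable, and what the defaults mean.

## Problem setting

A reaction optimization campaign searches a mixed condition space — a few
continuous variables with bounds in native units (residence time in
minutes, temperature in °C, catalyst loading in mol%) and a few
categorical variables (solvent, ligand, catalyst, up to ~8 levels each) —
for the conditions maximizing product yield (percent, in [0, 100]).
Experiments are expensive: tens, not thousands. Bayesian optimization
iterates three components: a probabilistic surrogate of the yield surface
fitted to all experiments so far, an acquisition function scoring
candidate conditions, and an optimizer that finds the acquisition argmax
to propose the next experiment.

The package's central claim is about *transfer*: when completed campaigns
for chemically related substrates exist, a multitask surrogate trained
jointly on those auxiliary tables plus the current campaign (MTBO) is more
sample-efficient than a single-task surrogate (STBO) started from scratch.

## Encoding conditions

Continuous variables are min–max scaled to [0, 1] by their declared
bounds; each categorical variable becomes a one-hot block in declared
level order. The encoded dimension is therefore (number of continuous
variables) + (total number of categorical levels). Scaling to a common
[0, 1] cube is our choice, not a given: it puts all dimensions on one
footing so a single family of length-scale bounds is meaningful across
variables with very different units. One-hot is the simplest encoding that
lets ARD length scales learn per-level relevance; descriptor-based
encodings are deliberately out of scope.

Relaxed one-hot vectors can only arise inside the acquisition optimizer,
and it never returns them: categorical combinations are enumerated
exactly. `decode_vector(..., categorical = "argmax")` exists for
completeness and resolves ties toward the lowest declared level index.

## Single-task surrogate

The surrogate is a zero-mean GP over encoded conditions with the Matérn
5/2 kernel on the length-scale-weighted Euclidean distance, plus trainable
Gaussian observation noise. Yields are standardized to mean 0 / sd 1 per
fit; all user-facing quantities are de-standardized back to percent.

Choices that matter:

* **Observation noise.** A trainable noise variance σₙ² with floor 1e-6
  (standardized units²) is always present. Experimental yields are noisy,
  a noiseless GP is numerically fragile on near-duplicate conditions, and
  qNEI presupposes a noise model.
* **Jitter.** 1e-6·σ² is added to the covariance diagonal before
  factorization, escalating ×10 up to 1e-2·σ² before reporting failure.
  The jitter is part of the model covariance that the log marginal
  likelihood and its gradient see, so training and prediction are
  consistent.
* **Training.** Log marginal likelihood is maximized over
  log-transformed parameters by L-BFGS-B with analytic gradients, from 8
  restarts (one fixed default start, the rest randomized). Bounds: length
  scales in [1e-3, 1e3] on scaled inputs, noise in [1e-6, 10]. The
  restart count and bounds are conventions, exposed as arguments.
* **Degenerate inputs.** All-identical yields give sd 0; the
  standardization falls back to sd 1 and the fit lands on a near-zero
  signal variance rather than crashing.
* **Posterior covariance hygiene.** Predictive covariances are
  symmetrized as (C + Cᵀ)/2; the sampling path clips negative eigenvalues
  at zero.

`gp_state()` builds a fixed-hyperparameter state without training, which
is what the oracle tests and calibration studies use.

## Multitask surrogate

The intrinsic model of coregionalization: covariance between
(x, task t) and (x', task t') is B[t, t'] · m₅₂(x, x'). Design decisions,
each of which the data could not dictate:

* **Parameterization of B.** A Aᵀ + diag(d) with rank(A) = min(T, 2) by
  default. This keeps B positive semidefinite for every reachable
  parameter setting and controls parameter count at small T. The rank is
  a config argument.
* **Scale identifiability.** The input kernel's signal variance is fixed
  at 1; all output scale lives in B. Otherwise σ²·B is only identified up
  to a constant.
* **Per-task standardization.** Tasks may sit in different yield regimes
  (a sluggish substrate vs a reactive one); standardizing per task makes
  the task kernel describe *shape* correlation rather than offset
  differences. Constants are stored per task.
* **Shared structure.** All tasks share one set of ARD length scales and
  one noise variance — the ICM assumption in its plain form. Task-specific
  length scales are a non-goal.
* **Frozen auxiliaries.** Auxiliary tables never change during a
  campaign; only the main task accrues data.

The joint fit maximizes the joint log marginal likelihood with analytic
gradients (including the task-kernel factors). With T = 1 the model is the
single-task GP up to reparameterization; with B diagonal it decouples into
independent per-task GPs; with B all-ones and duplicated data it equals a
pooled fit — all three limits are asserted in the tests.

## Acquisition functions

**EI** uses the closed form (μ − y*)Φ(z) + σ̃φ(z), z = (μ − y*)/σ̃, with
y* the best observed yield (on the main task) and no exploration jitter.
At σ̃ = 0 it degenerates to max(μ − y*, 0).

**qNEI** draws joint posterior samples over the candidate batch together
with the observed inputs and averages
max(max over candidates − max over observed, 0). Using the *posterior at
the observed inputs* as the incumbent makes it robust to noisy
measurements, where the best observed value is a biased baseline. The
base normal samples are drawn fresh from the configured seed on every
call, so the acquisition surface is deterministic for the optimizer and
candidate evaluations share common random numbers. Candidates are
canonically ordered internally, making the value exactly invariant to
batch permutations. Defaults: 512 samples during optimization, 4096 in
verification; a minimum of 64 is enforced.

The campaign default is EI for simulated benchmarks and qNEI for live
suggestions — the split follows the intended use: simulation studies are
cheap and many, live flow-chemistry experiments are noisy.

## Acquisition optimization

Nothing in the problem dictates an optimizer, so this module is entirely
a documented design decision. Categorical level combinations are
enumerated exhaustively while their count is within `max_combinations`
(default 64; the realistic spaces here have ≤ tens), otherwise that many
are sampled uniformly. Per combination, the continuous block is maximized
by bounded L-BFGS-B from Latin hypercube starts (8 by default); all starts
are first scored in one vectorized pass and the best are polished (all of
them when at most two combinations are in play, the top two per
combination otherwise). Ties break toward the lexicographically smallest
encoded vector for reproducibility.

Two special cases are handled explicitly:

* **Duplicate suppression.** If the argmax coincides (within `tol` in
  encoded space) with an already-run condition, the best non-duplicate
  evaluated candidate is returned instead — otherwise noise-free
  benchmarks can stall on a converged incumbent.
* **Acquisition plateaus.** When every evaluated candidate has
  acquisition ≤ 1e-10 (a fully informed surrogate, e.g. a dense noiseless
  auxiliary table, or a converged campaign), the search falls back to
  maximizing the posterior mean: pure exploitation is the sensible limit
  of expected improvement as it vanishes everywhere.

## Latin hypercube initialization

Campaigns without prior data start from an LHS design: continuous
dimensions get a maximin Latin hypercube (exactly one point per
equal-probability stratum per dimension; the `lhs` package provides the
sampler), categorical dimensions are filled by cycling through the levels
and shuffling, so level counts differ by at most one. The historical
default for a 4-variable-class space is 16 (2⁴) initialization
experiments; the default STBO simulation setting here uses 8 so half the
budget is left for model-guided suggestions. MTBO campaigns with auxiliary
data skip initialization entirely — the initialization step exists only
when there is no previous information to learn from.

With zero main-task observations an MTBO campaign still needs a first
suggestion. The model is then trained on the auxiliary data alone and
predictions target the auxiliary task with the highest observed yield —
the first experiment exploits the most promising prior campaign and
deviates from its optimum only as far as the acquisition's exploration
pushes it. From the first main-task result onward the joint model takes
over.

## Synthetic benchmark family

The generator exists so transfer behavior can be studied with a known
ground truth. Each task's latent surface over the encoded space is

    z_t = sqrt(ρ) · z_shared + sqrt(1 − ρ) · z_t^indep

where the shared and independent components are drawn from the same
distribution: per categorical-combination offsets plus two Gaussian bumps
with random centers, widths and heights over the scaled continuous
coordinates. Because the components have equal marginal scale, ρ is
(approximately) the intertask surface correlation: ρ = 1 reproduces the
similar-auxiliary regime, ρ = 0 the divergent one, and the grid
correlation increases monotonically in between — this is the tested
control knob for transfer difficulty. The latent value maps to percent
through a logistic transform (yields saturate physically at 0 and 100);
observation noise is Gaussian with configurable sd, clamped to [0, 100]
afterwards, so noise is mildly heteroscedastic near the rails and the
interior noise magnitude is exactly `noise_sd`.

The default domain mirrors a realistic cross-coupling screen: residence
time 5–60 min, temperature 50–150 °C, loading 1–10 mol%, and one
8-level catalyst variable (two precatalysts × four ligands). Default
study conditions for the in-silico comparison are ρ = 0.8 (related but
not identical chemistry), noise_sd = 2 (a plausible HPLC-assay scatter),
a 96-point auxiliary table, campaign budget 20, and 20 repeats; these are
the conditions the acceptance checks run under. What the generator does
*not* emulate: discrete reactivity cliffs, systematic assay drift, and
non-Gaussian failure modes (e.g. catalyst death giving exact zeros) —
passing tests on this family says nothing about those.

`ground_truth_optimum()` scores campaigns: dense grid over all categorical
combinations (21 points per continuous dimension by default) followed by
bounded local refinement, which never decreases the grid incumbent.
`train_table_surrogate()` implements the emulator pattern — fit a
regression model to a completed experiment table and use it as a
noiseless benchmark. The surrogate is the package's own GP with
predictions clamped to [0, 100]; a neural-network emulator would be an
extension point, not a requirement, and would add a heavy dependency for
no tested benefit here.

## Campaigns and comparisons

`run_campaign()` executes fit → maximize acquisition → evaluate → append,
recording per-iteration conditions, measured and noiseless yields, and
acquisition values; `best_trajectory` is the running maximum of measured
yields. Model fits are not warm-started across iterations by default
(hidden state across iterations makes runs harder to reason about);
`warm_start = TRUE` adds the previous optimum as an extra restart. A fit
failure mid-run halts the campaign gracefully with the partial result and
the error recorded.

`compare_strategies()` repeats each configuration with derived seeds and
aggregates: mean best-yield trajectory with a 95% normal confidence
interval (mean ± 1.96·sd/√n — the classical large-sample construction;
nothing here warrants anything fancier), pooled categorical selection
frequencies over suggested experiments, and — when the benchmark has a
ground truth — per-run experiments-to-optimum. The default tolerance for
"reached the optimum" is 1 percentage point; the headline comparison uses
5% of the optimum instead, and runs that never reach it are counted as
budget + 1 when taking medians.

All randomness everywhere flows from user-visible integer seeds through
one documented derivation (a fixed affine map modulo 2³¹ − 1), so any
campaign on a noiseless benchmark is reproducible byte-for-byte from its
manifest.

## Problem sizes in the test suite

The oracle checks run at N ≤ 8 against dense solve()/determinant()
implementations, where exactness to 1e-8 is meaningful. Recovery and
transfer simulations use 20 seeded replicates at N = 40–60 in one
dimension — large enough for the planted structure to dominate sampling
noise at the asserted ≥ 80% rates, small enough to keep each fit well
under a second. The campaign comparison runs the full default study
(two strategies × 20 repeats × 28 or 20 experiments on the 12-dimensional
encoded default domain), which is minutes of CPU and is the dominant cost
of both the test suite and the acceptance script.

## Known limitations

* Exact GP inference is O(N³); campaigns beyond a few hundred total
  observations (main + auxiliary) would need sparse approximations,
  which are out of scope.
* The ICM shares one set of length scales across tasks; auxiliary
  campaigns whose yield surfaces vary on very different scales are
  modeled only through the task correlation.
* qNEI optimizes a Monte-Carlo surface; with few samples the optimizer
  can ride sampling artifacts (mitigated, not eliminated, by common
  random numbers).
* The plateau fallback makes converged campaigns re-suggest near the
  incumbent; on noiseless benchmarks this is the correct fixed point, on
  noisy ones duplicate suppression keeps some diversity.
* Selection-frequency summaries count suggested experiments only; with
  small budgets they are coarse (multiples of 1/(budget·repeats)).
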