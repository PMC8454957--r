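---
title: "Personalized Bayesian optimization: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized Bayesian optimization: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persbo)
```

`persbo` optimizes a noisy, expensive black-box — behavioral performance
under brain stimulation — over a small discrete hardware lattice, while
conditioning on a per-subject covariate. This vignette is the package's own
account of the method: what is modeled, which knobs matter, which choices
were genuinely open and how we settled them, and what the synthetic tests do
and do not establish.

## Scoring behavior: the EZ-diffusion drift rate

A stimulation block of two-choice trials is reduced to a drift rate `v` by
the EZ-diffusion closed forms, which invert accuracy and correct-response RT
moments under an unbiased (start point `a/2`) Wiener diffusion. The drift
rate is the quantity optimized because it folds speed and accuracy into one
rate of evidence accumulation, insulated from response conservativeness and
motor time.

Conventions we adopt (the method's inputs are silent on some of them):

* **Correct responses only** enter `mrt` and `vrt`. This is the standard EZ
  convention; error RTs are discarded.
* **Edge correction**: `pc = 1` becomes `1 − 1/(2n)` and `pc = 0` becomes
  `1/(2n)` so the logit is finite. `pc = ½` exactly carries no directional
  information: `estimate_ez()` returns `v = 0`, leaves `a` and `ter`
  undefined, and raises a `persbo_degenerate_drift` warning instead of
  silently emitting an infinite boundary.
* **Scaling constant** `s = 0.1`, the conventional diffusion scale,
  configurable everywhere. `v` and `a` scale linearly in `s` while `ter` and
  the implied accuracy are invariant, which the suite checks.

The objective is `f(x, p) = Vstim / Vbase`. The 50-trial baseline block is
split at random into two 25-trial halves, one yielding the ability
covariate `p`, the other the normalizer `Vbase`; using different halves
removes the mechanical correlation between covariate and score. The split
is a seeded uniform partition, reproducible by construction.
`simulate_trials()` provides the generative counterpart (Euler steps of at
most 1 ms, absorbing boundaries, decision-time cap of 10 s) and acts as the
independent oracle for the closed forms: simulated blocks at known
`(v, a, ter)` must round-trip through `estimate_ez()` with error shrinking
as `1/sqrt(n)`.

## Coordinates, normalization, blinding

The decision space is discrete hardware: 46 frequencies × 16 active
currents in the burn-in phase (736 points) and 46 × 17 including sham in the
optimization phase (782). Inputs are mapped affinely to the unit cube;
outputs are standardized to mean zero, unit variance at every refit.
Standardization constants are stored so raw-scale predictions are always
recoverable, and it also guarantees that acquisition argmaxes are invariant
to affine transforms of the raw score (tested by scaling by 7 and shifting
by 3).

Two normalization choices deserve a note:

* **Current is normalized over the fixed bounds [0, 1.6] mA in both
  phases.** Normalizing each phase over its own sampled range would move
  identical physical settings to different kernel-space locations once sham
  enters the space; the burn-in simply never samples 0 mA.
* **The ability covariate is normalized over configured bounds**, default
  `[0, 0.2]` (bracketing typical baseline drifts around 0.055), not over
  the accumulating data. Running min-max renormalization would silently
  shift all previous training points between refits. Values outside the
  bounds are clipped with a warning.

Double-blinding is kept by a seeded random bijection between grid points and
opaque 3-digit codes, persisted as JSON. The original study-style scheme is
not recoverable from examples, and a random bijection is the only coding
that provably leaks no ordering of current (sham is indistinguishable from
active codes).

## The personalized GP surrogate

The surrogate over `z = (x, p)` uses a product of exponentiated-quadratic
kernels — one over the two stimulation coordinates with a shared length
scale `sigma_l`, one over `p` with `sigma_p` — plus i.i.d. observation
noise `sigma_n2`. Three numerical decisions:

* **Noise enters once, on the diagonal of the product kernel.** Writing the
  noise inside the stimulation kernel and then multiplying kernels would
  multiply the noise by the `p`-kernel, which is not a valid i.i.d. noise
  model; the additive placement matches `y ~ GP(m, k + sigma_n2*delta)`.
* **The Kronecker delta is keyed on the observation index, not coordinate
  equality**, so repeated measurements at one grid point carry independent
  noise — required for retesting outliers to reduce uncertainty rather than
  being treated as duplicates.
* **Jitter of 1e-8** is added to the diagonal before the Cholesky
  factorization; predictive variances are clipped at zero; the query term
  excludes noise, so the posterior variance never exceeds the unit prior
  variance.

Hyperparameters are estimated by maximizing the log marginal likelihood
with L-BFGS-B in log-space, with analytic gradients (verified against
finite differences at 1e-4), box bounds `sigma_l, sigma_p ∈ [1e-2, 10]`,
`sigma_n2 ∈ [1e-4, 4]` — comfortably enclosing the few-tenths length scales
and up-to-2 noise variances typical on this scaling — and multi-restart
initialization (first start at `0.2/0.3/0.1` or the previous fit, remaining
starts log-uniform under a seed). With a very large `sigma_p` the `p`-kernel
factor approaches 1 and the personalized model provably collapses to the
standard two-input surrogate; the suite checks numerical agreement at
`sigma_p = 1e6` and on datasets with constant `p`. The surrogate is refit
from the full included history before every use; because the refit is a pure
function of the log, the state is replayable and the implementation caches
at most one fit per state.

## Acquisition

Expected improvement is the default, computed in closed form on the
standardized scale with the incumbent `f⁺` equal to the best included
observation across all subjects. EI is defined as exactly zero wherever the
predictive standard deviation is zero — including when the mean exceeds the
incumbent — since a fully determined point can contribute no expected
improvement; this is asserted against a Monte-Carlo evaluation of
`E[max(Y − f⁺, 0)]` elsewhere in the space. GP-UCB is retained with a
configurable `kappa` and a Srinivas-style schedule helper. Because the grid
never exceeds 782 points, acquisition maximization is exhaustive and exact;
ties within 1e-12 of the maximum are broken by a seeded uniform draw.

## The sequential protocol

Defaults mirror the intended study design: 50 subjects × 3 blocks, the
first 60 assignments (20 subjects) drawn uniformly at random from the
sham-free burn-in grid — with replacement, since the assignment scheme
within the burn-in is otherwise unspecified — and EI-driven selection at
the subject's `p` afterwards. Burn-in is counted in assignments, not
subjects, so an aborted subject cannot desynchronize the phases. Raw scores
at or above 3.6 (configurable; `NULL` disables) are flagged as outliers:
they stay in the log but never enter covariance matrices. Exclusion is
policy rather than mathematics, so it is applied at update time and fully
reversible from the log.

Participant-level cross-validation (80/20 by subject, all blocks of a
subject kept together) fits the same personalized GP as a plain regression
of the raw score on (frequency, current, baseline) and reports MSE on the
raw score scale, the scale on which score spreads are meaningful.

## The Hartmann-3D benchmark

The three-dimensional negated Hartmann function stands in for
(frequency, current, ability): personalized BO models all three dimensions
but can only *choose* the first two — the third is an exogenous
per-iteration draw `p_t ~ U[0,1]`, exactly as baseline ability is exogenous
per subject. Standard BO models the two controllable dimensions and
experiences `p` as unexplained variance; random search draws uniformly.
Design choices where the benchmark design was open:

* Noise levels default to `{0, 0.01, 0.1, 0.5, 1, 2}` — six values spanning
  zero and the upper end of noise variances estimated from behavioral data.
* The `p_t` sequence is shared across algorithms within a repeat, pairing
  the comparison and reducing between-algorithm variance.
* "Best found value" is the noise-free objective at the best queried point,
  so the trace measures true progress and is monotone by construction.
* The "identified optimum" is the posterior-mean argmax — over `(x, p)` for
  pBO, over `x` (paired with the true optimum's `p`) for BO, and the best
  noisy query for random search, which has no model. The argmax grid is
  30 points per dimension by default: on posteriors whose fitted length
  scales are a few tenths, refining from 30³ to 50³ moves the argmax by
  less than one grid cell while quintupling the dominant cost, so 30 is the
  default and the resolution is configurable.
* Each GP run spends its first 10 of the 60 evaluations on random
  initialization and refits hyperparameters (2 restarts, warm-started from
  the previous fit) every iteration.

The true optimum location is itself computed at run time by grid sweep plus
local refinement, not hard-coded.

## The synthetic cohort generator

The generator is the package's stand-in for an (undeposited) human cohort,
and its defaults are the study conditions: 50 subjects, abilities drawn
from Beta(2, 5) rescaled to `[0, 0.2]` — right-skewed, most subjects on the
low-ability end, mean near 0.057 — and a 50-trial simulated baseline block
per subject, actually split and EZ-scored, so the covariate and normalizer
carry realistic estimation noise. A baseline block whose halves produce a
non-positive drift estimate is redrawn (a real study would not enroll an
unusable baseline); this truncates the very lowest abilities slightly.

The ground-truth response surface is a Gaussian bump over unit
(frequency, current) whose peak travels linearly from high
frequency/current at `p = 0` to low frequency/current at `p = 1` — the
qualitative personalization structure the optimizer must recover — with
base level 0.9, amplitude 1.8 and width 0.3, keeping expected scores inside
the realistic 0.5–3.8 band; at the default observation noise (SD 0.25) the
simulated score spread is of the same order as the ~0.54 SD seen in real
data. The seed jitters the path endpoints (±0.05) and width (±10%) so
replicated recovery experiments face different ground truths, while the
high-to-low direction is preserved by construction. Observation noise
enters either through finite-trial diffusion simulation (the full
pipeline) or through an additive-Gaussian fast path used where a test needs
many replicates; "low-noise" recovery experiments use the fast path at
SD 0.05.

What passing these tests shows — and does not. They show the closed loop
can recover a smooth, unimodal-per-slice, baseline-dependent optimum within
one grid step from 150 observations, and that modeling the covariate beats
ignoring it under matched conditions. They do not show robustness to
learning or fatigue across blocks (not modeled), to multimodal true
surfaces (available as a stress-test option, not a default claim), to
model-mismatched noise, or to covariate measurement error beyond what
25-trial EZ estimation induces.

## Problem sizes and determinism

The shipped suite runs everything at sizes chosen to make the statistical
assertions sharp but cheap: GP-oracle equivalence on 100 random instances
of up to 10 points (tolerance 1e-8), hyperparameter recovery on 20 cohorts
of 200 GP samples (within a factor of 2, ≥ 80% of seeds), the EZ round
trip at 10,000 trials (±10%), the benchmark at 10 repeats × 3 noise levels
× 60 iterations, and 20 full 150-observation protocol replicates. Every
random draw descends from an explicit integer seed through a deterministic
stream-splitting hash, so any run, proposal, or benchmark cell can be
replayed exactly from its logged seeds.

## Known limitations

* Only the EZ closed forms are implemented; no likelihood-based diffusion
  fitting, and no modeling of trial-level dependencies.
* The GP assumes Gaussian noise and a stationary product kernel; no Matérn
  option, sparse approximation, or non-Gaussian likelihood.
* One shared length scale covers both stimulation coordinates, following
  the single-`sigma_l` parameterization; anisotropy between frequency and
  current is absorbed by the unit-cube scaling.
* Acquisition is strictly sequential; no batch proposals.
* Whether the incumbent `f⁺` should be global or local to a neighborhood in
  `p` is a genuine modeling question; the global convention is implemented.
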