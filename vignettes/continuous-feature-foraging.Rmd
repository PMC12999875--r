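---
title: "Modelling continuous-feature visual foraging with hueforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling continuous-feature visual foraging with hueforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hueforage)
```

## The task and the model

In a continuous-feature foraging task an observer sees a display of 60
coloured disks — 30 targets whose hues are drawn from a truncated Gaussian
on a circular, perceptually linearised colour space, and 30 distractors
drawn from two uniform bands flanking that distribution — and clicks targets
one after another until a randomised quota of 18–28 target selections ends
the trial. Because every selected item disappears, the display's feature and
spatial statistics change with each click: foraging is sampling without
replacement.

hueforage implements a generative model of this selection sequence. At click
$j \ge 3$ every remaining item $i$ receives the weight

$$
w(i) = \exp\{-\rho_c\,C(i) - \rho_s\,S(i, j\!-\!1)
  - \rho_\delta\,\delta(i, j\!-\!1) - \rho_\psi\,\psi(i, j\!-\!1, j\!-\!2)\},
$$

and is selected with probability $w(i) / \sum_k w(k)$ over the remaining
set, which contains unclicked targets *and* distractors (distractor hues are
simply a continuation of the feature space; clicking one removes it without
advancing the quota). The four predictors are

* $C(i)$ — circular hue distance (in just-noticeable differences, JND) of
  item $i$ from the designated hue, the centre of the target distribution.
  Positive $\rho_c$ means colour tuning toward the most probable hue.
* $S(i, j-1)$ — hue distance from the previously selected item. Positive
  $\rho_s$ means a preference to stay close in colour space ("switch"
  aversion).
* $\delta(i, j-1)$ — Euclidean distance from the previous selection, in
  normalized display units (the unit square), so $\delta \in [0, \sqrt 2]$.
* $\psi(i, j-1, j-2) \in [0, 1]$ — the relative change in direction of
  travel: 0 directly ahead, 0.5 for a right-angle turn, 1 for doubling
  back. Negative $\rho_\psi$ encodes a preference for reversals.

The first click is uniform over all 60 items — equivalent to picking a hue
with probability proportional to its onscreen frequency when every item
carries one hue token. The second click omits the $\psi$ term, which is
undefined without a penultimate selection; we prefer omission over imputing
a dummy travel direction. A degenerate zero-length travel vector (impossible
with distinct positions, but guarded) yields the uninformative midpoint
$\psi = 0.5$.

Two conventions matter for interpreting coefficients. Hue predictors are in
raw JND; one index step is one JND, and the largest circular distance on the
48-hue space is 24. Spatial predictors use coordinates normalized to the
unit square — a proximity prior centred at 15 is only sensible on a 0–1.4
distance scale. $C(i)$ is measured against the generating distribution's
designated centre for the relevant experiment half, not a per-trial sample
mean: the distribution parameter is what the display realises noisily.

## The synthetic-data generator

`distribution_spec()`, `session_spec()`, `generate_display()` and
`generate_session()` emulate the study design: 48 equally discriminable
hues on a circle; target hues from a Normal(`mu`, 4 JND) truncated at
±8 JND (16-JND total span) and rounded to the nearest hue index; distractor
hues uniform on the 8 integer offsets 11–18 JND from `mu` on a uniformly
chosen side, leaving a 3-JND gap beyond the truncation bound on each side;
items placed on distinct cells of an 8×8 grid spanning 11° of visual angle,
jittered ±0.5° per axis and then mapped affinely to the unit square; 48
trials per session split into halves whose designated hue differs by 24 JND
(the opposite pole of the colour circle); and a per-trial quota drawn
uniformly from 18–28. Rounding truncated-Gaussian draws to integer indices
is the simplest faithful map onto the discrete hue list; the jitter is
uniform per axis. Block structure beyond the half split is metadata only and
is not generated.

What the generator deliberately does not emulate: actual CIE colorimetry or
luminance (the hue index is the unit of analysis), response times, fatigue
or learning within a half, and any deviation from exact 1-JND spacing
between adjacent indices. Tests that pass on generated data therefore
validate the sampling-without-replacement machinery and the estimation
pipeline, not claims about human observers.

`simulate_trial()` and `simulate_experiment()` run the model forward:
participant coefficient vectors are drawn once per participant from the
group model $\theta_p = \beta + \mathrm{diag}(\sigma) L z_p$ ($L$ the
Cholesky factor of the random-effect correlation matrix), fresh displays are
generated, and every click is sampled from the model probabilities. The
default `group_parameters()` fixture — $\beta = (0.08, 0.15, 12, -0.5)$,
$\sigma = (0.03, 0.05, 3, 0.3)$, identity correlation — lies inside the
priors' bulk and produces qualitatively task-like behaviour: mean-seeking,
colour-switch-averse, strongly proximity-biased, mildly reversal-preferring.
It is a fixture choice for recovery studies, not an empirical claim.

## Inference

`fit_foraging()` samples the hierarchical posterior with a No-U-Turn
sampler built into the package (doubling trajectories with the
slice-sampling acceptance rule, dual-averaging step-size adaptation to a
0.8 target acceptance, and windowed estimation of a diagonal metric).
Priors are the model's standard choices: $\rho_c, \rho_s \sim N(0, 0.1)$,
$\rho_\delta \sim N(15, 5)$, $\rho_\psi \sim N(0, 1)$ (second argument an
SD), Exponential(rate 5) on the group-level SDs, LKJ($\eta = 2$) on the
random-effect correlation matrix. The LKJ shape is not pinned down by the
model description; $\eta = 2$ weakly favours the identity and is
configurable through `prior_spec()`, as are all scales.

Implementation choices a user may care about:

* **Parameterization.** Random effects are non-centered by default
  ($\theta_p = \beta + \mathrm{diag}(\sigma) L z_p$ with standard-normal
  $z_p$), which is robust when group-level SDs are weakly identified — the
  relevant regime with a handful of participants. A centered option exists
  (`parameterization = "centered"`); on our simulated benchmarks it
  produced divergent transitions driven by the group-SD funnel, so it is
  not the default.
* **Gradients.** The sequential-choice likelihood and its gradient are
  evaluated in C++ in log space (max-shifted log-sum-exp per choice set).
  Normal, exponential and standard-normal prior gradients are analytic; the
  small tanh/Cholesky correlation transform (at most 6 dimensions) is
  differentiated by central differences with step $10^{-6}$.
* **Warmup schedule.** 75 step-size-only iterations, then doubling metric
  windows, then 150 step-size-only iterations; the metric is the regularized
  sample variance of the unconstrained draws. Tree depth is capped at 9
  during warmup (early, poorly-adapted steps otherwise spend thousands of
  gradient evaluations per iteration) and at 10 during sampling. A dense
  metric option exists but is noisier than the diagonal at the draw counts
  used here.
* **Convergence.** Rank-normalized split-chain r-hat is computed for every
  stored parameter (fixed effects, group SDs, correlations, and each
  participant coefficient) — the estimator to which the 1.01 convergence
  threshold belongs; by default the fit errors when any r-hat reaches 1.01.
  Effective sample sizes use the combined-chain autocovariance estimator
  with Geyer's initial monotone sequence. Note that the maximum of r-hat
  over ~46 parameters is itself a noisy statistic: at 2 chains × 500 draws
  even perfectly independent draws place it near 1.005, and realized values
  for this posterior vary by a few thousandths from seed to seed.
* **Determinism.** Chain $c$ seeds R's RNG with `seed + c - 1`; the C++
  sampler consumes R's RNG stream in exactly the same order as the
  reference R implementation (`hueforage:::nuts_chain`), and the two
  produce bit-identical chains — a property the test suite asserts.

Posterior summaries report means, medians and 53/89/97% highest-density
intervals (`hpdi()`: the shortest contiguous interval over the sorted
draws, ties resolved toward the lower bound), and `participant_effects()`
gives per-participant 97% HPDIs.

Sessions generated with a mid-experiment distribution shift are naturally
fitted one half at a time (`half = "first"` / `"second"`): the model is
stationary within a half, and the halves are presented separately in the
study design. Recovery benchmarks use a shift-free session so that all
trials share one distribution and a single fit uses them jointly.

## Model comparison

Three nested variants are supported: the full model, a spatial-plus-switch
model ($\rho_s, \rho_\delta, \rho_\psi$), and a purely spatial model
($\rho_\delta, \rho_\psi$); excluded coefficients are removed from the
parameter vector (equivalently fixed at zero in the likelihood), and the
random-effect structure covers exactly the included coefficients.
`psis_loo()` estimates the expected log predictive density by
leave-one-out cross-validation with Pareto-smoothed importance sampling;
the unit of cross-validation is the single selection event, so the
pointwise log-likelihood matrix has one column per click (first clicks
contribute their constant $-\log 60$). The smoothing fits a generalized
Pareto distribution to the largest $\min(0.2S, 3\sqrt S)$ importance
ratios by the Zhang–Stephens profile-posterior method, replaces them with
expected order statistics truncated at the raw maximum, and flags events
with shape $\hat k \ge 0.7$. `compare_foraging_models()` anchors the best
model at an ELPD difference of zero and reports paired-difference standard
errors.

## Problem sizes used by the test suite

The suite exercises the pipeline at deliberately scaled-down sizes chosen
as the package's benchmark settings: generator invariants on 1,000
displays; likelihood conservation by brute-force enumeration on a 4-item
display; simulator/likelihood consistency from 10,000 two-click trials on a
5-item display; prior recovery from a likelihood-free fit; parameter
recovery from 8 participants × 12 trials per seed over five seeds, each fit
with 2 chains of 500 warmup + 500 draws; model comparison on 5 participants
× 8 trials with 2 × 300/300 fits per variant; and the depletion signature
from 480 strongly colour-tuned trials. The recovery benchmark checks that
every fixed-effect posterior mean has the generating sign and that the 97%
HPDIs cover the truth for at least three of the four parameters in at least
four of five seeds.

## Known limitations

Inter-target selection times are carried through the data model (`rt`
columns survive I/O and feed `rt_descriptives()`) but are never modelled.
The model is stationary within an experiment half: no trial-order learning,
no fatigue. The likelihood treats the designated hue as known to the
analyst; inferring it from behaviour is out of scope. With two chains of
500 draws the split-r-hat convergence gate is conservative and can trip on
sampling noise even when posterior summaries are stable; when that happens,
more draws — not different data — are the remedy.
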