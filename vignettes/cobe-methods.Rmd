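---
title: "Correlated Beta dose optimisation: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated Beta dose optimisation: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobe)
```

This vignette is the package's account of the science it implements: the
Continuous Correlated Beta Process (CCBP) model for dose–response, the four
dose-optimisation strategies built on top of it, the synthetic scenario
generator used to exercise them, and the numerical and design decisions made
along the way.

## The dose-optimisation problem

An early-phase vaccine trial must pick, from a set of candidate doses, the
one that maximises a utility of the binary efficacy and toxicity
probabilities — with fewer than a few hundred participants, and without
knowing the shape of the dose–response curve. Doses are vectors of 1–3
components in `[0,1]` (prime, boost, second-boost amounts, each rescaled so
0 is the smallest dose worth considering and 1 the largest). A
*dose-optimisation approach* bundles four choices: a dose–response model, a
rule for picking trial doses as data accrue, a rule for nominating the final
dose, and a discretisation of the dosing domain.

## The CCBP model

Each dose `i` and response channel `r` carries a beta distribution
`Beta(alpha_ir, beta_ir)`, initialised at the uniform `Beta(1,1)` when
nothing is known. A plain beta-Bernoulli scheme would add 1 to `alpha_ir`
(response) or `beta_ir` (no response) only at the exact tested dose; the
CCBP instead adds the kernel similarity `K(d_i, d_j)` to *every* dose `i`
when dose `j` is tested. We use the squared-exponential kernel

$$K(d_i, d_j) = \exp\!\Big(-\sum_{o=1}^{H} (d_{io}-d_{jo})^2 / l_o^2\Big),$$

which is symmetric, equals 1 exactly when the doses coincide, is strictly
positive at any finite distance, and factorises across administration axes.
The update is pure addition, so batches are order-independent, the total
mass added to a channel equals the summed similarities (a conservation law
the tests verify to 1e-9), and letting every `l_o -> 0` recovers the
uncorrelated scheme — which is exactly how the naive comparator strategies
are implemented.

The length hyperparameters default to 0.2 (single administration), 0.25 per
axis (prime/boost) and 0.4 per axis (three administrations). They are the
values used in the simulation study this package supports and are plain
configuration inputs (`kernelSpec()`); the package deliberately ships no
procedure for estimating them from data. Unequal per-axis lengths are
allowed. Kernel values are never thresholded: truncating tiny similarities
to zero would be an unstated approximation, and the exact form costs
nothing. Efficacy and toxicity channels may use different kernels, though by
default they share one.

### Expert priors

An expert prediction `p` with confidence `c >= 0` (in units of
participants' worth of data) is encoded as the prior
`Beta(p c + 1, (1-p) c + 1)`, whose mode is `p` for any `c > 0` and which
degrades gracefully to `Beta(1,1)` at `c = 0`. In the prior-elicitation
experiments, a "correct" expert predicts the true probability at every dose
and an "incorrect" one predicts its complement, at strength `c = 3` (strong)
or `c = 20` (very strong).

## Utilities

Two utilities are provided. *Maximum efficacy* is `U = p_eff`. The *utility
contour* is

$$U = 1 - \Big[\big(\tfrac{1-p_{\mathrm{eff}}}{1-\pi_E}\big)^{\rho} +
\big(\tfrac{p_{\mathrm{tox}}}{\pi_T}\big)^{\rho}\Big]^{1/\rho},$$

whose zero-utility contour passes exactly through the clinician anchors
`(pi_E, 0)` and `(1, pi_T)`. The anchors and curvature are trial-specific
clinical judgements; the shipped defaults (`pi_E = 0.5`, `pi_T = 0.65`,
`rho = 2`) are illustrative values in the style of published
efficacy–toxicity contour designs, not recommendations. Utilities below zero
are kept as-is — a dose worse than the zero contour should rank below one on
it. Every simulation evaluates ground-truth utility and strategy-internal
utility with the same specification object, so the two can never drift
apart.

## The four strategies

**CoBe** (`doaCobe`): CCBP on the dense grid; Thompson sampling (draw one
probability per dose per channel, take the argmax of sampled utilities, once
per participant in the cohort); final dose by argmax of the utility of exact
posterior medians. Medians use the inverse regularised incomplete beta
(`qbeta`) rather than sampling so that final selection is deterministic up
to declared tie-breaking. All exact ties, everywhere, are broken uniformly
at random from the strategy's RNG stream.

**Parametric** (`doaParametric`): dose–efficacy is a logistic sigmoid of a
per-axis quadratic latent score (allowing peaks), dose–toxicity a sigmoid of
a linear score; both are refitted after every cohort by maximum likelihood.
Because separation (e.g. an all-responder cohort) makes the raw MLE diverge,
the likelihood always includes pseudo-data: one success and one failure at
weight 0.5 at the extremes and midpoint of each axis (corners plus centre in
2D/3D). The optimiser is BFGS from three fixed starting points at relative
tolerance 1e-8 (the latent quadratic likelihood can be multi-modal), so fits
are deterministic given data. Trial doses are drawn softmax-proportionally
to `exp(U_i / T)` with default temperature `T = 0.07` on the unit utility
scale — concentrated near the predicted optimum but still exploring. Both
the pseudo-data weight and the temperature are exposed as arguments. No
linear toxicity model is defined for three administrations, so
three-administration contour problems are refused at construction.

**Adaptive naive** (`doaAdaptiveNaive`): as CoBe but with the uncorrelated
update (domain membership required) on the coarse grid — adaptive, but each
dose learns only from itself.

**Uniform naive** (`doaUniformNaive`): the conventional design; every cohort
is one sweep of the coarse grid (cohort size must equal the domain size), so
300 participants on a 9-dose grid give 33 cohorts and use 297 of them.

## Scenario generator

Scenarios supply the simulation ground truth: a domain, a utility, and true
efficacy/toxicity curves. The catalogue covers the qualitative families a
vaccine developer might face — gently/sharply saturating, gently/sharply
peaking, decreasing, undulating and flattened-peak single-administration
efficacy; synergistic/antagonistic saturating, peaking, high-dose-decline
and one-dose-dominant prime/boost surfaces; independent-peaking and
two-of-three-maximal three-administration surfaces; gradually/sharply
increasing and either-dose-increasing toxicity. The closed forms are this
package's own: normalised Hill curves for saturation, Gaussian bumps for
peaks (a sixth-power exponent for the flattened plateau), a linear trend
plus one sinusoid for undulation, and additive Hill marginals with an
interaction term (and, where needed, a high-dose decline factor) for
surfaces. Default parameters were chosen once to look like realistic
vaccine curves: probabilities well inside `[0,1]`, peak efficacies around
0.8–0.9, floor around 0.05–0.1. Two deliberate properties: the sharply
peaking curve's optimum (0.9 at dose 0.5) exceeds the best value on the
coarse 6-dose grid by ~0.4, so the catalogue can exhibit the coarse-grid
ceiling that separates naive from model-based strategies; and the
two-of-three-maximal surface scores any two maximal administrations above
all three maximal.

Constructors validate their output range on the domain grid and error on
parameters that escape `[0,1]`. Curves are evaluated lazily per dose, so a
dense strategy grid and a coarse one share a single ground truth. Efficacy
and toxicity outcomes are sampled independently within a participant — the
joint law within a participant is not modelled, which matters only if one
wanted within-person efficacy–toxicity correlation.

What the generator does *not* emulate: population heterogeneity, time
structure, non-binary endpoints, or real immunogenicity data. Passing
simulations show the strategies behave as designed under known smooth ground
truths; they do not certify performance on any particular real vaccine.

## Simulation engine and metrics

`runTrial()` executes the adaptive loop — propose a cohort (size 6 by
default for adaptive strategies), sample outcomes, absorb, nominate — and
records two metrics after every cohort: the *true* efficacy/utility of the
currently nominated dose (how good the recommendation is) and the cumulative
efficacy (count of responders) or cumulative utility (`n` times the utility
of the empirical response fractions) among participants so far (how ethical
the trial was). The interim nomination is computed after every cohort; in
practice one might skip it until the end, but computing it throughout shows
how recommendation quality grows with trial size. If the participant total
is not a multiple of the cohort size, the last cohort is simply truncated.

`runStudy()` crosses scenarios with strategies for a number of replicates;
each replicate's seed is a 31-bit hash of the master seed and the pairing's
names, so results are bit-reproducible and adding a strategy never perturbs
existing streams. `aggregateTrials()` reports per-cohort means with 95%
confidence intervals — Student-t on the replicate means by default, with a
percentile bootstrap as an option since either is defensible — plus
theoretical reference lines: the domain-wide max/min of the true metric and
`n` times each for the cumulative metrics (the upper line is attainable only
by an oracle dosing everyone at the true optimum).

The problem sizes used in this package's own test suite are scaled-down
study conditions chosen to make the stochastic checks sharp but cheap: 20
replicates of 300 participants for the strategy-ordering comparison, 50
single-cohort replicates for the prior-elicitation orderings, and a
100,000-draw brute-force sampler as the independent oracle for Thompson
selection frequencies.

## Numerical decisions

* Posterior medians and credible intervals via `qbeta`; no sampling in final
  dose selection.
* Conservation bookkeeping uses plain summation; the 1e-9 tolerance is
  comfortable for the ≤ 10^4 observations a trial of this size can produce.
* `updateState()` accepts off-grid observation doses (the kernel is defined
  continuously); only the uncorrelated update demands domain membership.
* MLE parameters are unconstrained; stability comes from pseudo-data, not
  box constraints.
* Degenerate inputs: zero observations still yield a proper parametric fit
  (pseudo-data alone); cumulative utility at `n = 0` is defined as 0; a
  cohort of identical posteriors makes Thompson sampling exactly uniform.

## Known limitations

Binary endpoints only; no stopping rules or escalation/de-escalation
constraints (all strategies are compared without them, so comparisons are
internally fair, but real trials would add them); kernel lengths are inputs,
not estimated; the parametric comparator is a single model family per
channel, so its performance on, say, undulating curves partly reflects
misspecification — which is the point of the non-parametric alternative, but
means the comparator is not the best conceivable parametric design; and the
three-administration case has no toxicity model for the parametric strategy.
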