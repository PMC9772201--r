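---
title: "Memorability and value-based choice: models, design, and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memorability and value-based choice: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(memchoice)
```

## The scientific question

Some stimuli are reliably remembered and others reliably forgotten, across
observers — an intrinsic, item-level property usually summarized as a
*memorability score*. If more memorable options are retrieved earlier or more
vividly, memorability could bias everyday value-based decisions ("which snack
do I pick?") even when it carries no value information. memchoice implements
the full analysis chain needed to ask that question with a two-session
design:

1. a **continuous recognition task** that measures each item's memorability
   as corrected recognition (CR = hit rate − false-alarm rate);
2. a **rating phase** giving each participant's subjective value for every
   item, and a **two-alternative choice phase** over value-matched and
   value-mismatched item pairs;
3. **conditional mixed-effects models** asking whether the absolute
   memorability difference |Δmem| predicts choices once value differences
   are controlled by a median split, with likelihood-ratio tests, Bayes
   factors for the null, simulation-based power, and a drift-diffusion
   decomposition of the joint choice/RT data.

Because the original participant data are not required, the package ships a
seeded synthetic-cohort generator whose defaults reproduce the structure of
the study it emulates: 138 items, 199 recognition participants (29 targets
and 109 fillers each), and 44 choice participants with 138 bespoke pairs
each.

## The synthetic cohort

**Latent items.** Each item carries a logit-scale hit propensity
`theta_mem`, a logit-scale false-alarm propensity `phi_fa`, and a population
mean value `mu_value` on the 0–10 rating scale. `theta_mem` and `mu_value`
are joined by a Gaussian copula; the copula parameter is rescaled by a
numerically integrated factor so the *Pearson* correlation of the realized
marginals equals the requested `mem_value_corr` (default 0.15, the item-level
correlation magnitude the analyses anticipate; the marginal transforms would
otherwise attenuate it by a few percent). The memorability marginal family is
deliberately configurable ("normal" by default, "logistic" available): no
particular family is implied by the CR measurements, only a smooth unimodal
spread. The value marginal is a scaled Beta(2, 2): smooth, mid-scale-heavy,
supported exactly on [0, 10]. With the default logit parameters
(`theta_mean = 0.5`, `theta_sd = 0.9`, `phi_mean = -2.2`), the simulated
item CRs have a median near 0.5 and a range of roughly −0.1 to 0.9, matching
the spread the recognition task is expected to produce.

**Recognition.** Streams interleave 29 twice-shown targets (repeat more than
60 trials after the first showing), 109 fillers, and short-gap (1–7 trial)
filler repeats for a configurable fraction of fillers (default 0.5; the
design only requires "some"). Stream construction is rejection sampling:
target positions are drawn and paired rank-wise under the gap constraint,
then fillers and their short-gap repeats are scheduled over the free slots,
with a bounded retry loop (default 1000) and a validator that re-checks
every invariant. A press on any repeat is a hit with probability
`inv_logit(alpha_p + theta_i)`; a press on any first showing is a false
alarm with probability `inv_logit(gamma_p + phi_i)`; `alpha_p, gamma_p` are
zero-mean Gaussian participant effects (response-criterion variation).

**Ratings and choices.** Ratings are `mu_value` plus participant-by-item
Gaussian noise, clipped to the slider (continuous values are kept: the
slider is continuous and no granularity is implied). The logistic choice
backend draws choose-right with log-odds
`beta0 + beta_value * dvalue + beta_mem * dmem` (per-subject Gaussian
coefficient variation) and lognormal RTs whose log-mean decreases in
|Δvalue| (default −0.04 per z-unit, the magnitude the RT analysis expects);
draws beyond the 3 s deadline become no-response trials and are dropped
downstream, mirroring the task deadline. The DDM backend replaces this
with a Wiener first-passage simulation (below). `beta_mem = 0` — the
default — is the null world in which memorability has no causal path to
choice.

All randomness flows from one root seed through named substreams
(`substream_seed(seed, "ratings")`, ...), so any stage can be regenerated in
isolation and identical configs give bit-identical outputs.

## Memorability scoring and consistency

CR is computed per item over the participants for whom the item was a
target; the exact identity `cr = hit_rate - fa_rate` is kept, and items
never assigned as a target are flagged missing rather than scored zero.
"Correct rejection" — needed by the performance exclusion (fewer than 3 hits
or fewer than 3 correct rejections) — is defined here as a no-press on *any*
first presentation, target or filler: the task text does not define it, and
this reading maximizes counts and matches standard usage.

Split-half consistency repeats, for `n_iter` (default 1000) iterations:
random disjoint participant halves → per-half item CR → Spearman correlation
across items (average ranks for ties); the reported statistic is the mean
rho over iterations. The permuted-chance distribution needs care: the
observed statistic is a *mean* over many splits of one dataset, so its null
distribution is dataset-level, and single shuffled-rho draws are far more
dispersed than the statistic they are meant to calibrate (a fixed null
dataset can easily carry a conditional mean rho of ±0.15 purely from its
realized item totals). Each chance draw therefore relabels items *within
each participant* — the exchangeable transformation under "no item
signal" — and recomputes the mean split-half rho with the identical
procedure. The p-value uses the add-one estimator
`(1 + #{null means ≥ mean rho}) / (n_null + 1)`, which can never return 0;
with `n_null = n_iter = 1000` its resolution reaches the conventional
"p < 0.001". This makes the p-value uniform under a no-signal generator
(checked by a KS test over 200 simulated cohorts). The nested resampling is
done with indicator-matrix multiplications; the full-design case
(199 participants × 138 items, 1000 × 1000 resamples) runs in about two
minutes. Items unscored in one half of an iteration are dropped pairwise
and counted.

## Choice design

Within participant, items are ranked by value (ties broken uniformly at
random under a participant-scoped seed, so a strict total order always
exists). Close pairs join adjacent ranks (1-2, 3-4, ...); far pairs join
rank k with rank k + n/2. The half-offset is the only far distance that
tiles an even item set into disjoint pairs, so that the n pairs are all
distinct and every item is used exactly twice (once per pair type); the
offset is configurable for other designs. Sides and trial order are
randomized; covariates are the right-minus-left differences of
within-participant z-valued ratings (Δvalue) and across-item z-scored CR
(Δmem, computed once over items and shared by all participants), their
absolute values, and the pair's summed memorability (SumMem). All z-scores
use the sample SD (n−1).

The conditional analyses restrict trials by a **pooled** median split
across the final sample's responded trials (the "half of the choice trials"
reading), strictly-below-median in the low half with ties assigned in stable
trial order until the halves are as equal as possible.

## Screening

Three single-pass criteria, combined by disjunction:

* **side bias** — p(choose right) strictly more than 2 sample SDs from the
  cohort mean (one pass on the full cohort; an SD of zero excludes no one);
* **fast RT** — responded-trial RT below 300 ms on strictly more than half
  of trials (the criterion's "average RT ... in more than half of the
  trials" is read trial-wise, the only well-formed reading);
* **value sanity** — a per-participant simple logistic regression of
  choose-right on Δvalue; excluded when the slope is non-positive or its
  Wald p ≥ 0.05 (Wald chosen where the test family is unstated;
  configurable). Perfect separation — a perfectly value-consistent chooser —
  is detected and resolved by data direction with p treated as significant,
  so such a participant is never excluded. Non-convergent fits are flagged
  and excluded.

## Inference

Choice models are mixed-effects logistic regressions fit by maximum
likelihood with a Laplace approximation over by-subject random effects
(lme4, bobyqa), with by-subject intercepts and random slopes for every
fixed effect and an unstructured (correlated) random covariance — the
random-effects structure is stated by the design, the covariance is the
package's choice. Odds ratios are `exp(beta)` per z-unit with Wald 95% CIs;
p-values come from likelihood-ratio tests against a refit without the focal
fixed effect, random structure retained. Convergence failures fall back to
uncorrelated random effects, then to a random intercept only, always
flagged. Tie trials (exactly equal value or memorability) are dropped from
the "chose higher-value / more memorable" codings. RT models are linear
mixed models on natural-log RT in seconds, fit with `REML = FALSE` so the
LRTs are valid ("logistic transform" of RT is read as a log transform —
the −0.04-scale betas are consistent with log-seconds; a logit-on-scaled-RT
switch is provided). No multiplicity correction is applied; each model is
reported separately.

**Bayes factors.** The memorability model is refit by MCMC (JAGS), with
independent by-subject Gaussian intercepts and slopes (half-Cauchy SD
priors) and a zero-mean Gaussian prior of SD `prior_width` (default 1, on
standardized covariates) on the focal coefficient. BF01 is the
Savage–Dickey density ratio at zero — appropriate because the hypothesis is
a point null on one coefficient — with the posterior ordinate from a
Gaussian kernel density over the draws. Effective sample size and split-chain
R-hat are recorded and flag the fit rather than fail it. The sensitivity
table refits over widths {0.1, 0.25, 0.5, 1, 2}. BF magnitudes depend on
this family and are reported as such; only their direction and
width-sensitivity behaviour are asserted by tests.

**Power.** `power_simulation()` is a full-pipeline simulation: per
replicate it simulates ratings, builds pairs and trials, generates choices
with the focal odds ratio injected as the memorability coefficient, screens
participants, median-splits, fits, and LRT-tests. Two deliberate semantics
make the injected effect *be* the effect size under test:

* the power template decouples the latent memorability/value copula
  (`mem_value_corr = 0`): with the copula on, a value-mediated pathway adds
  a positive apparent |Δmem| effect on top of the injected coefficient, so
  the generated total effect would exceed the nominal one;
* rejection counting is directional by default (`direction = "positive"`:
  LRT p < α *and* a positive coefficient), i.e. the power to detect the
  hypothesized more-memorable-chosen-more effect. This matters because a
  slightly *negative* generating effect (odds ratio 0.97) is genuinely
  resolvable two-sided at tens of thousands of trials — with ~69 trials per
  participant a two-sided LRT reaches ~60% rejection at n = 500 — while the
  probability of a significant *positive* estimate stays near zero at every
  n. `direction = "any"` restores two-sided counting and is what the
  calibration tests use (null world → rejection ≈ α).

The many fits use a relaxed bobyqa stopping radius (`rhoend = 1e-4`, no
derivative check); on an n = 500 benchmark this reproduced the
default-tolerance LRT statistic to five decimals at roughly half the cost.

## Drift-diffusion decomposition

The Wiener first-passage density uses the standard small-time/large-time
series with an automatic switch to whichever needs fewer terms at the
requested accuracy (default 1e-10 truncation error); upper-boundary
densities reuse the lower-boundary series under (v, w) → (−v, 1 − w), and
the closed-form absorption probability
`(1 − e^{−2vz}) / (1 − e^{−2va})` serves as an independent check. Path
simulation is Euler–Maruyama (Rcpp) at `dt = 1e-4` with unit noise; paths
unabsorbed by 10 s are recorded as no-response. Fitting is per-participant
maximum likelihood: drift is linear in trial covariates, the relative start
point goes through an inverse-logit link (guaranteeing z ∈ (0, 1)),
boundary separation is log-parameterized, and `t0` is kept below 95% of the
participant's minimum RT. Inter-trial variability parameters (sv, sz, st0)
are fixed at zero. Group inference is a one-sample t-test of each weight
across participants, with boundary/non-convergent fits flagged and dropped
from the group tests. A hierarchical Bayesian variant is a known difference
from fitting practice elsewhere; the per-participant MLE asks the same
scientific question (is drift, or start point, related to Δvalue/Δmem?) in
a deterministic, desk-scale way.

## Numerical choices and degenerate inputs

* Zero-variance raters get z = 0 and a flag (candidate exclusion), not an
  error; z-scoring is idempotent to 1e-12.
* Spearman ties use average ranks; ranking ties in the choice design are
  broken uniformly at random under seed control.
* Exact-tie trials are dropped from directional choice codings and logged.
* Constant-RT inputs are rejected as degenerate rather than fit.
* The stream builder errors after its retry cap when constraints are
  unsatisfiable; the validator re-verifies every generated fixture.
* Separation in per-participant logistic screening is resolved by data
  direction (kept if positive).

## Test-scale choices

The test suite exercises everything at sizes chosen to keep a full run in
the tens of minutes on one CPU: the power ceiling at grid {44, 500} with 40
replicates per point (the acceptance script runs the full
{44, 100, 250, 500} × 100), type-I calibration with 200 null replicates at
n = 44, split-half p-value uniformity over 200 no-signal cohorts of 12
participants, DDM simulator/density agreement at n = 4000 per grid point,
DDM group recovery with 12 simulated participants × 138 trials × 3
replicates, and Bayes-factor/LRT direction agreement over 6 short-chain
replicates.

## What the generator does not capture

Synthetic cohorts have no attention lapses, no dropout, no comprehension
failures, no sequential dependencies (fatigue, streaks), no semantic
structure among items, and rating noise that is homoscedastic by
construction. Passing tests therefore demonstrate that the *pipeline* is
correct and calibrated — that it finds effects that are there, at the
advertised rates, and not effects that are absent — not that any particular
empirical conclusion holds in real data. The interchange CSV schema and
`load_external_trials()` exist precisely so the identical analysis code can
be pointed at collected data.

## Known limitations

* BF01 magnitudes are family- and prior-dependent; treat them as evidence
  direction plus sensitivity curve, not as portable constants.
* The Euler–Maruyama simulator has O(√dt) first-passage bias; at the
  default `dt = 1e-4` this is below the Monte-Carlo noise of the test
  sample sizes, but much larger `dt` will fail the density agreement
  checks.
* The per-participant DDM MLE needs on the order of 80+ responded trials;
  with fewer, estimates are flagged rather than trusted.
* Stream construction assumes the default geometry is feasible (it is for
  138 items); radically different item counts may need a wider target gap
  or filler fraction to remain constructible.
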