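---
title: "Decision-bound modeling of cross-modal information-integration category learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-bound modeling of cross-modal information-integration category learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(catbound)
library(dplyr)
```

## The scientific problem

In information-integration category learning, two categories live in a
two-dimensional stimulus space and neither dimension alone separates them:
accurate classification requires combining both dimensions along a diagonal
decision boundary, a computation associated with gradual, procedural
learning rather than explicit rules. `catbound` implements the
computational core of a cross-modal variant of this paradigm — the visual
dimension is the density of lit pixels in a 150 × 150 pixel box, the
auditory dimension the frequency of a pure tone — together with the
decision-bound (general recognition theory) analysis used to infer, from a
participant's responses alone, which classification strategy they used, and
the covariate-adjusted group analysis used to compare delay groups in a
consolidation design (a 15-min delay, an overnight lab stay, a 12-h sleep
delay, and a 12-h wake delay). No human data ship with the package; a
synthetic-observer generator stands in for participants so the entire
design and analysis pipeline can be exercised end to end and validated by
parameter recovery.

## The category space

Each category is an equal mixture of two isotropic bivariate-Gaussian
components on an abstract 0–100 "level" scale per dimension (A at
(26.67, 50.00) and (50.00, 73.33); B at (50.00, 26.67) and (73.33, 50.00);
all SDs 10, equal priors). The space is continuous and deliberately not
clamped to [0, 100] — the paradigm's own follow-up scales run from level
−25 to 125, so levels outside the nominal range are meaningful; the "101
levels" of pixel density are the display granularity of the physical
stimulus, not of the abstract space.

Levels are realized physically as `pixels = round(850 * 1.0181^level)`
(half-up rounding, so level 0 gives 850 lit pixels of the 22,500 in the
box) and `frequency = 220 * 2^(level/120)` Hz (220 Hz at level 0, 392 Hz
at level 100 after rounding; frequencies are kept continuous internally and
rounded only for display). A note on the pixel ceiling: the growth formula
evaluated at level 100 gives 5110.49, i.e. 5110 lit pixels after half-up
rounding; the formula is treated as normative throughout.

```{r realize}
realize_pixels(c(0, 50, 100))
round(realize_frequency(c(0, 50, 100)))
```

Exemplar sets are sampled per participant with `sample_exemplars()`. Each
category's draw is split equally across its two components (an odd
remainder is allocated by a seeded draw), and by default each component's
sample is affinely standardized per dimension so that its sample mean and
SD equal the component parameters *exactly*. This mirrors how
per-participant stimulus sets are equated in the paradigm: every simulated
participant sees the same statistical structure through unique exemplars.
Normalization is per component and per dimension; cross-dimension
covariances are not matched, which is innocuous here because the components
are axis-aligned with zero correlation. Standardization needs at least two
draws per component and errors otherwise.

Screen side is assigned by a line orthogonal to the category boundary
(`x + y >= 100` presents on the left by default). Which half-space maps to
which side is a display convention with no categorical information for
this symmetric structure, so the polarity is a configurable argument
rather than a fixed fact.

## Optimal boundary and its accuracy

A linear boundary is parametrized by the direction of its unit normal and
its signed offset from the origin, with category A on the positive-normal
side. This avoids both the redundancy of a three-parameter line
description and the vertical-line singularity of intercept/gradient form
(`as_intercept_gradient()` converts for reporting). For axis-aligned
Gaussian components, expected accuracy of any linear boundary is analytic:
project each component onto the boundary normal and take the Gaussian CDF
of the mean's signed distance. `optimal_boundary()` maximizes this with a
deterministic coarse grid (1° in angle, 1 level in offset, both label
orientations) plus Nelder-Mead refinement.

```{r boundary}
b <- optimal_boundary(ii_structure())
b
attr(b, "accuracy")
```

For the default structure the optimum is the main diagonal `x = y`, and
its expected accuracy is `pnorm(23.33 / (10 * sqrt(2)))` = 0.9505 — a 95%
ceiling with 5% irreducible category overlap.

## Synthetic observers and the experiment generator

An observer (`observer_spec()`) responds through exactly the probabilistic
rule the fitting module assumes: the probability of an A response is the
Gaussian CDF of the stimulus's signed margin in units of an internal-noise
SD, optionally mixed with a lapse probability (uniform guess) and a
timeout probability (no response within the 8-s window; scored incorrect,
excluded from likelihoods). Simulator and likelihood share one
implementation of this rule (`response_prob_a()`), so parameter recovery
tests the fitting machinery, not a translation layer.

`simulate_experiment()` assembles the full design: four delay groups,
Session 1 (two 60-trial learning blocks, then test 1), a consolidation
delay, and Session 2 (test 2, two more learning blocks, test 3), with
fresh normalized exemplar sets per participant and phase and 30 A + 30 B
trials per block in random order. Learning is modeled as between-phase
parameter change only — the study design measures accuracy at block
granularity, so a trial-level learning rule would add parameters that
nothing in the analysis surface could constrain.

The default observer population was chosen once, by calibration against
the qualitative accuracy trajectory this paradigm produces in practice
(means rising from the mid-0.60s in the first learning block to the
mid-0.70s by the final test, between chance 0.5 and the 0.95 ceiling), and
not revisited:

* initial strategy mix: 15% random guessers, 45% unidimensional rule
  users (split equally across dimensions), 5% conjunction users, 35% GLC
  users, with criteria and boundaries jittered (SD 5 levels, 5°) around
  the task-appropriate values;
* internal noise: population median 25 levels at the first block, with a
  log-normal participant multiplier (log-SD 0.15), shrinking across
  phases (multipliers 1.00, 0.85, 0.78, 0.78, 0.70, 0.66, 0.62) as
  learning proceeds;
* strategy dynamics: at each phase transition a random guesser adopts a
  rule with probability 0.3; rule users switch to the integrative GLC
  strategy with baseline probability 0.05 per transition;
* delay-group effects, applied only after test 1: a noise multiplier
  (1.00, 0.92, 0.92, 1.05 for 15-min, overnight-lab, 12-h sleep, 12-h
  wake) and a one-shot extra rule-to-GLC switch probability across the
  delay (0.05, 0.25, 0.25, 0.00) — sleep consolidates, in this generator,
  by denoising and by promoting integration;
* lapse rate 2%; timeouts off by default (the schema carries them for
  completeness).

These group effects are artifact constructs — the study reports no
quantitative model of strategy change across the delay — and
`null_experiment_config()` equalizes them for calibration runs. The
generator deliberately omits features of real data: no within-block
learning, no feedback-driven trial-by-trial updating, no reaction times,
no points or reward effects, and no sleep physiology. Passing tests
therefore show that the analysis pipeline recovers what this generative
family injects, not that real participants behave like these observers.

All randomness flows from one master seed through deterministic
per-participant, per-phase substreams, so any participant regenerates in
isolation (`simulate_participant()`) and identical seeds give
byte-identical serialized output.

## Decision-bound models, fitting, and AIC classification

Four model families describe a participant's partition of the space:
unidimensional criteria on either dimension (2 parameters: criterion and
noise), a conjunction rule with a criterion on each dimension (3: two
criteria and one shared noise term, which keeps the printed parameter
count), the general linear classifier (3: boundary angle, offset, noise),
and random guessing (0). A single noise SD per model pools perceptual and
criterial noise; `tidy()` also reports its square for readers who think in
variances. The conjunction rule's canonical orientation is "low pixel
density AND high tone frequency is A"; the other three orientations can
be fitted best-of via `db_fit_options(conjunction_orientations = ...)`
without changing the parameter count, since the orientation is a discrete
rule choice.

Fitting minimizes the negative log-likelihood (probabilities clamped to
`[1e-10, 1 - 1e-10]` so degenerate fits stay finite) with multi-start
bounded local optimization: 19 stratified-random starts plus one
data-driven start (criteria between the response-class means; the GLC
normal along the difference of class means), `nlminb` with relative
tolerance 1e-6, criteria bounded to [−25, 125] (the follow-up scale
range), noise to [0.01, 200], offsets to [−200, 200], and the GLC normal
angle to [0, π). Everything is deterministic given the options seed. The
random family needs no optimization: its log-likelihood is `n * log(0.5)`
exactly, so its AIC is exactly `2 n log 2`.

`classify_strategy()` fits all families and selects the minimum AIC, with
ties broken toward fewer parameters and then a fixed family order. The
"1D" family is represented by the better of the two unidimensional fits at
k = 2, matching how strategy tables in this literature report a single 1D
column; which dimension won is kept in `best_sub_family`. With 60–120
trials per test, AIC discrimination among these families is genuinely
noisy — a parametric family beats the true random model on roughly 15% of
coin-flip observers by capturing chance correlation, and conjunction
observers are the hardest to separate from the GLC. The recovery harness
(`strategy_recovery()`) quantifies exactly this confusion matrix rather
than assuming it away.

## Group analysis

`summarize_accuracy()` scores proportion correct per participant and phase
(timeouts incorrect); `chance_test()` runs per-group one-sample t-tests
against 0.5, flagging zero-variance groups as degenerate instead of
erroring mid-pipeline. `ancova_adjusted_means()` implements the one-factor,
one-covariate ANCOVA with the sequential covariate-first decomposition:
the group F compares the covariate-only and covariate-plus-group linear
models, adjusted means are raw group means shifted along the pooled
within-group slope to the grand covariate mean, and the effect size is
SS_group / SS_total. Homogeneity of slopes is not tested (the analysis
surface being reproduced reports a single pooled slope), and no
multiple-comparison correction is applied inside the pipeline — that is
reporting policy, not computation. The published inferential model for
strategy shifts (a mixed-effects logistic regression) is deliberately
replaced by descriptive GLC-proportion deltas (`strategy_shift_summary()`):
fitting GLMMs is off-the-shelf statistics, and the descriptive table is
the part specific to this design.

`run_recovery()` closes the loop: simulate under a configuration, run the
test-3 ANCOVA with test-1 as covariate, and report the rejection rate —
the type-I error rate under a null configuration, power under an injected
effect.

## Numerical choices and problem sizes

* Half-up rounding for pixel counts (a count of lit pixels, not banker's
  rounding); frequencies unrounded internally.
* Screen-side ties (`x + y = 100`) go left under the default polarity.
* Optimal-boundary search: 1° × 1-level grid, then Nelder-Mead to
  relative tolerance 1e-12 on the objective; accuracy is analytic, so no
  Monte-Carlo error enters the optimum.
* Likelihood clamp 1e-10; optimizer tolerance 1e-6; 20 starts — all
  overridable in `db_fit_options()`.
* Fit floor: 10 labeled trials (configurable); below it the likelihood
  surface is too flat for the three-parameter families.
* The packaged test suite validates the stochastic claims at sizes a
  single CPU handles comfortably: strategy recovery with 50 observers per
  family at 120 trials, type-I calibration with 500 replicate experiments
  of 4 × 23 participants, and Monte-Carlo boundary-accuracy checks with
  10^6 draws. The same functions scale to larger runs by changing the
  arguments.

## Known limitations

* Observers are stationary within a phase; any within-block learning in
  real data is absorbed into between-phase parameter changes.
* The conjunction family shares one noise SD across its two judgments; a
  two-noise variant would change the printed parameter count.
* The GLC angle bound [0, π) fixes the response labeling to the
  orientation used by learners of this structure; a pathological observer
  with fully inverted labels would be fit as a poorly fitting member of
  the family rather than its mirror image.
* ANCOVA treats per-participant proportions as Gaussian outcomes; with 60
  trials per test this is a good approximation (and the type-I
  calibration confirms it for the simulated design) but it is not a
  binomial GLMM.
* Human strategy proportions cannot be reproduced without the human data;
  recovery results validate the pipeline on its own generative family
  only.
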