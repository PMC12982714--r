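---
title: "Simulating and analysing optimal cognitive offloading experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing optimal cognitive offloading experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offloadr)
```

## The task and the measures

In the value-based offloading task a participant works through 16 trials.
On each trial, 5 target circles (embedded among 15) must eventually be
dragged to an instructed side of a box. The participant can rely on
internal memory, earning 10 points per correct target, or place the
circles immediately as external reminders, earning a smaller value `v`
(2--9 points, each value presented twice) per correct target. Four trials
are designated forced-internal and four forced-external (values split by
parity, which parity is forced-internal randomised between participants);
a choice that conflicts with the designation is overwritten. The remaining
8 free-choice trials end early, contributing strategy choices but no
accuracy data.

From one participant's log the pipeline derives:

* **ACC~FI~, ACC~FE~** — percent correct pooled over targets within the
  forced-internal and forced-external trials (20 Bernoulli outcomes each,
  so ACC~FI~ has 5-point resolution).
* **OIP** (optimal indifference point) — the reminder value at which an
  unbiased participant should be indifferent,
  `OIP = 10 * ACC_FI / ACC_FE`. We leave it unclamped: values outside
  2--9 are rare but legal and carry real information about bias.
* **AIP** (actual indifference point) — the 50% crossing of a cumulative-
  normal psychometric function fitted by maximum likelihood to the 16
  binary strategy choices, with the location box-constrained to 2--9.
* **Reminder bias** = OIP − AIP (positive = pro-reminder), and its
  absolute value.
* **Metacognitive bias** = confidence − ACC~FI~ at each timepoint
  (positive = overconfident), and its absolute value.
* **Hindsight bias** — the directional shift of recalled initial
  confidence toward actual performance:
  `sign(ACC_FI − conf_pre) * (conf_recalled − conf_pre)`.

All 16 choices enter the AIP fit, including overwritten and
early-terminated trials: strategy choices are collected before the trial
unfolds, so every trial yields a valid choice regardless of what happens
afterwards.

## The generative participant model

The simulator exists so the whole analysis chain can be exercised, and
parameter recovery quantified, without any behavioural data. The papers
this paradigm comes from report no generative model, so the model here is
the simplest mechanism set consistent with what is known about the task:

* **Memory**: per-target accuracy is Bernoulli with rate `p_int`
  (internal) or `p_ext` (external). No learning across the 16
  experimental trials.
* **Choice**: the probability of choosing reminders on a trial with value
  `v` is `pnorm((v − s) / sigma_choice)`, a probit around the subjective
  indifference point `s = 10 * (conf/100) / p_ext_believed − delta`.
  Confidence drives offloading (less confident, more reminders);
  `delta > 0` captures a confidence-independent pro-reminder preference
  such as effort avoidance; `p_ext_believed` defaults to 1 (participants
  assume reminders work).
* **Intervention**: during the 5 forced-internal practice trials,
  protocols that elicit predictions update confidence by the error-driven
  rule `c <- c + eta * (acc − c)`, with `eta = eta_pred` when only
  predictions are made and `eta = eta_pred + eta_fb` when performance
  feedback is shown. Explicit metacognitive feedback applies a
  multiplier (`meta_gain`, default 1) to `eta_fb`: the default encodes no
  extra learning from labelling over/under-confidence, which is the
  empirically observed pattern, while leaving the knob available for
  sensitivity analyses.
* **Reports**: every confidence report is the latent confidence plus
  Gaussian noise (`conf_noise`), rounded to an integer and clipped to
  0--100 (a slider). Latent confidence is frozen after the pre-task
  report.
* **Recall**: recalled initial confidence is distorted linearly toward
  actual internal accuracy with weight `lambda_hind` before noise.

### Default cohort conditions

Group populations share one set of distributions; the additive
intervention effects arise purely from the protocol flags gating the
learning rates. Defaults (clipped-normal, `c(mean, sd)`): `p_int`
(0.66, 0.18) and `p_ext` (0.97, 0.05), matching the accuracy regime of
online cohorts on this task; `conf0` (50, 25), broad and on average
underconfident relative to typical accuracy; `eta_pred` (0.05, 0.02),
weak, because making predictions alone has not been found to improve
calibration; `eta_fb` (0.25, 0.10), substantial, so five feedback cycles
move confidence most of the way toward experienced accuracy; `delta`
(0.5, 1.0) points of mild pro-reminder preference; `sigma_choice`
(1.0, 0.3) points; `lambda_hind` (0.25, 0.15), producing group-mean
hindsight biases of a few percentage points; `conf_noise` (5, 2).

What the simulator deliberately does **not** emulate: reaction times,
within-trial dynamics, learning during the experimental block,
participant attrition, and any dependence of choice noise on value
magnitude. Passing end-to-end tests therefore shows that the analysis
chain recovers the structure this model generates — not that real data
satisfy the model.

## Numerical choices in the AIP fit

The psychometric family is the cumulative normal (the default of the
fitting package traditionally used with this task); only location and
slope are estimated, with no guess/lapse parameters. The location is
box-constrained to [2, 9] and the slope to [0.05, 10] per point: below
0.05 the curve is flat over the whole value range, above 10 it is a step
at the resolution of unit-spaced values, so nothing outside the box is
identifiable from 16 choices. Optimisation is L-BFGS-B from nine starts
(locations 2.5/5.5/8.5 x slopes 0.3/1/3); ties go to the highest
likelihood, then the lowest location. All-reminder and all-internal
response vectors short-circuit to the bounds (2 and 9). The test suite
checks the fit against an exhaustive location x slope grid search
(location step 0.01): on 200 random response vectors the two agree to
within 0.05 points.

One estimator property worth knowing: adding a reminder choice at a low
value usually lowers the AIP, but when the extra choice makes the
responses badly inconsistent the maximum-likelihood slope collapses and
the near-flat curve's location can drift to a bound, *raising* the AIP.
Both the optimiser and the independent grid search show this, so it is a
property of the bounded two-parameter MLE itself, not a numerical
artefact; the property tests assert monotonicity only while the refitted
slope stays well-determined.

## Exclusion cascade

Six pre-registered-style criteria run in a single pass, in order:
(a) ACC~FI~ < 10%; (b) ACC~FE~ < 70%; (c) negative Pearson correlation
between value and reminder choice; (d) ACC~FI~ > ACC~FE~; (e) reminder
bias and (f) signed pre-task metacognitive bias more than 2.5 MAD units
from the within-group median. Choices made where the criteria are
underspecified: the MAD uses the 1.4826 consistency scaling (the
convention the 2.5 threshold originates from; a raw-MAD switch is
provided); the reference medians/MADs for (e) and (f) are computed among
survivors of (a)--(d); constant choice vectors have undefined
correlation and are retained under (c) rather than excluded, since
all-reminder or all-internal responding is a legitimate boundary
strategy, not evidence of random choice; and the cascade is not iterated
to convergence — a single pass matches how such criteria are typically
pre-registered and keeps the excluded set independent of iteration
order.

## Inferential layer

The mixed Group x Time ANOVA is computed from the subject-means /
difference-scores decomposition: the between stratum tests Group on
subject means, the within stratum tests Time and the interaction on
difference scores. With unbalanced groups the Time effect uses the
unweighted mean of group mean changes (a Type-III-style choice —
documented here because sums-of-squares conventions only matter once
exclusions unbalance the groups; with balanced data all conventions
coincide, and the tests verify the implementation against base R's
`aov` error-strata on balanced designs). Partial eta squared is
`F * df1 / (F * df1 + df2)` per effect.

The linear contrast across the four additive groups uses equally spaced
weights proportional to (−3, −1, 1, 3), with `sum(w^2/n)` handling
unequal group sizes. Welch (Satterthwaite df) and pooled-variance t
tests are both provided because the planned analyses use both —
fractional printed dfs imply Welch, integer N−2 dfs imply pooled — and
Cohen's d always uses the pooled SD. A summary-statistics entry point
reproduces group comparisons from printed means/SDs/ns. One-tailed
tests halve the two-tailed p in the hypothesised direction. No
multiple-testing correction is applied anywhere, matching the planned
directional analyses. Sample-size planning inverts the noncentral-t
power function (`ncp = d * sqrt(n/2)`, `df = 2n − 2`) for the smallest
per-group n reaching the target power.

Degenerate inputs are handled explicitly: a one-sample t of identically
null scores reports t = 0 (no evidence) rather than failing; a
two-sample t with two constant, equal samples is undefined and says so;
collinear predictors abort the AIP regression; empty groups abort the
ANOVAs.

## Problem sizes and reproducibility

The workflow scripts simulate the two designs at their planned sizes (82
per group for the two-group design, 104 per group for the four-group
design), chosen to match the sample-size calculations the designs were
powered with. Property suites use 100--500 Monte-Carlo replicates and
200-vector oracle comparisons, sizes at which the checked quantities are
stable to well inside their asserted tolerances. Every random stage
flows from a single master seed: per-participant seeds are drawn once
from the master stream, so any participant can be regenerated in
isolation and reruns are byte-identical.

## Known limitations

* The AIP is bounded, so cohorts with many extreme responders compress
  variance near 2 and 9; recovery statistics are reported on the bounded
  scale.
* OIP is a ratio estimator from 20 + 20 Bernoulli trials; at low ACC~FE~
  it is noisy, which is part of why the exclusion cascade floors ACC~FE~.
* The generative model's additive intervention effects are encoded in two
  learning rates; it cannot by construction produce patterns like
  feedback *worsening* calibration.
* Criterion (c) uses the strict rule r < 0 without a significance
  requirement; with 16 trials this excludes some unlucky-but-rational
  responders, mirroring the conservative reading of the criterion.
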