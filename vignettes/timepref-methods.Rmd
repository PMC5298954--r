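---
title: "Measuring time preferences and asking whether they predict anything"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring time preferences and asking whether they predict anything}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timepref)
```

## The problem

People constantly choose between a smaller reward available sooner (SS)
and a larger reward available later (LL). A *time-preference test* asks a
respondent to make such choices about money and summarizes them as a
scalar score, scored here so that greater values always mean greater
patience. Two constructs are of interest:

* **Patience** — the overall willingness to wait, summarized for monetary
  choices by a one-month discount factor $d \in (0, 1]$: $d\,x$ dollars
  now is worth $x$ dollars delivered a month later.
* **Nonstationarity** — how expressed patience changes when a common
  *front-end delay* is added to both options. Each test family therefore
  has a *near* variant (SS available today) and a *far* variant (both
  options pushed back one month); a far score above the near score is the
  classically self-control-relevant pattern of planning to be more
  patient in the future.

The statistical question the package is built around is the distinction
between **association** and **prediction**. In-sample fit statistics
($R^2$, Efron's $R^2$) measure how well a model can be made to agree
with data it was trained on; *predictive accuracy* is how well the model
estimates values it has never seen, which is what matters when a test is
used for assessment. Association is optimistically biased as an estimate
of prediction because of overfitting, so predictive accuracy is measured
by tenfold cross-validation against a predictor-free baseline.

## The three test families

**Fixed test.** Seven forced choices from the classic medium-magnitude
monetary-choice items, ranked 1..K by the discount rate at which each
item's two options are equally attractive (rank 1 is \$54 vs. \$55, rank
2 is \$47 vs. \$50, ...). Scoring finds the *most consistent rank*: the
candidate rank $r \in \{1, \dots, K{+}1\}$ predicting LL on exactly the
$r - 1$ highest ranks that matches the largest number of observed
choices. Ties are resolved by averaging the tied ranks, so a few
non-integer scores are possible. The reported score is $2r - 2$. The
affine transform and $K$ are configurable: the instrument's medium set
has nine items and we ship all nine (`kirby_medium_bank(9)`), the
default administration uses the first seven ranks, so default scores lie
in $[0, 14]$. No switch-point scheme over seven items can produce the
sometimes-quoted 0–20 range, which would need eleven rank levels; rather
than guess, both knobs are exposed.

**Bisection test.** An adaptive forced-choice test that estimates $d$
directly by the probabilistic bisection algorithm. A discretized
posterior over $d$ (uniform prior on a 1024-point equispaced grid on
$[0,1]$) is queried at its median: the LL amount is drawn uniformly from
\$15–\$95 and the SS amount is set to `round(median * LL)` (at least
\$1). An LL choice is evidence that $d$ exceeds the query ratio, so the
grid mass above the query is rescaled to $p_c$ and the rest to
$1 - p_c$, with $p_c = 3/4$ the assumed probability that a choice
reflects the respondent's true preference. After 20 trials the score is
the final posterior median. Numerical choices: the update conditions on
the *rounded* stimulus ratio SS/LL actually shown, not the pre-rounding
median; the posterior median is the smallest grid point with cumulative
mass $\ge 0.5$ (deterministic and grid-exact); a query with all mass on
one side is uninformative and leaves the state unchanged. Two catch
trials with amount ratios 0.07 (LL overwhelmingly better) and 1.13 (the
"later" option also smaller, hence dominated) are interleaved at seeded
random positions; they never update the posterior and only count
failures.

**Matching test.** Ten free-response trials: SS is drawn uniformly from
\$1–\$95 and the respondent fills in the LL amount that would make them
indifferent, to cent precision. The score is the median of SS/LL —
again a discount factor. Responses below SS are flagged (they feed the
exclusion rules) but still enter the median; with an even trial count
the midpoint of the central order statistics is used.

## Criterion variables, coding, exclusions

The criterion questionnaire covers behaviors theoretically linked to
patience: tobacco use, exercise, diet, flossing, credit-card behavior,
saving, gambling, and body mass. The declarative coding rules
(`study1_coding_rules()`) reproduce the standard transforms: log(x+1)
for exercise hours; percentages clipped to [0.005, 0.995] and
logit-transformed; BMI = weight/height² dichotomized at ≥ 25
("overweight"); gambling, late fees and subpayments dichotomized at
> 0 (credit rules only for credit-card users); flossing cut into three
ordered categories (< 1/week, 1–6/week, daily or more). The coded table
carries each column's DV family (continuous, binary, ordinal). We keep
packs of cigarettes per week as a tenth, log1p-coded continuous DV
alongside the tobacco binary, so the default coded set has ten columns.

Exclusions: a subject is dropped from the main sample for a nonsensical
(out-of-domain) questionnaire answer, for ≥ 3 failures of the 8
session-1 catch trials, or for ≥ 3 LL-below-SS matching responses among
the 40 session-1 matching trials. The retest sample additionally drops
subjects who finished session 2 in under 3 minutes. "Nonsensical" is
operationalized as out-of-domain values (negative counts, percentages
outside [0, 100], physiologically impossible heights/weights), with
configurable bounds.

## The evaluation engine

For each criterion and test family the model has four terms — intercept,
near score, far score, and their interaction — and the family matches
the DV: ordinary least squares (continuous), maximum-likelihood probit
(binary), maximum-likelihood ordinal probit (ordinal). *Association* is
the in-sample $R^2$ / Efron's $R^2$ (for ordinal DVs, an Efron-style
statistic on the expected category index with categories coded 0, 1,
2). *Predictive accuracy* comes from tenfold cross-validation
(balanced, unstratified, seeded folds; a training fold with a degenerate
response falls back to an intercept-only fit rather than aborting the
run): out-of-fold RMSE for continuous DVs against the population SD,
and the proportion of correct argmax classifications for discrete DVs
against the modal base rate.

*Reliability* is treated as self-prediction: round-1 scores are used
unaltered as predictions of round-2 and round-3 scores, so bias is
penalized and no cross-validation is needed. The report gives PVAF
($1 - \mathrm{MSE}/\mathrm{Var}$, population variance, so identity
scores give exactly 1), absolute-error quantiles (median, 90th, 95th;
linear-interpolation convention), bias (mean target minus predictor),
Kendall's $\tau_b$, and Pearson's $r$. For comparability with
correlation-based reports, `pvaf_from_correlation()` squares a
correlation ($r = 0.75 \rightarrow 0.56$, $r = 0.33 \rightarrow 0.11$).
*Convergent validity* is clipped cross-validated mutual prediction:
linear out-of-fold predictions of one test's scores from another's,
clipped to the DV's legal range, summarized by PVAF. Score descriptives
report quartiles (type-7 linear interpolation) and MAD; the default MAD
is the *median* absolute deviation from the median (unscaled), with the
*mean* absolute deviation available via `mad_type = "mean"` since the
absolute-error analyses use the latter as their baseline.

## The patience-pair analysis

The large-survey arm works with a pair of free responses: the smallest
extra amount that would convince the respondent to wait one month, and
one year, for a \$1000 prize (any nonnegative integer; higher demands
mean less patience). Two models are contrasted per criterion:

* the **log model**, with nine terms: intercept, $\log$ of each
  response (0 when the response is 0 — the zero dummy carries that
  information), a response-is-zero dummy per item, and the four
  non-trivial one-way interactions (the two within-item products are
  identically zero and excluded). Binary criteria use probit ML;
  continuous criteria use median regression (quantile-0.5 loss), with
  MAE metrics and the mean absolute deviation from the median as
  baseline, so heavy tails are not weighted quadratically.
* the **nominal model**, the most flexible predictor possible on the
  pair: every distinct (month, year) response pair is a class, except
  that all singleton pairs are pooled into one class; each class
  predicts its training mode (binary; ties broken by the global mode,
  residual global ties to the smaller value) or median (continuous).
  Pairs unseen in training route to the pooled singleton class — the
  model's pool of rare responses — or, when no singleton exists, to the
  global fallback.

With 746 distinct pairs of which 392 are singletons, the class count is
$746 - 392 + 1 = 355$. The nominal model demonstrates overfitting: its
in-sample association beats the log model's essentially by
construction, while its cross-validated accuracy falls behind.

Association screens use nonparametric tests — Wilcoxon rank-sum for
binary criteria (patience as the DV, as is conventional) and Kendall
$\tau_b$ for continuous ones — with step-down Holm–Bonferroni correction
at the family sizes implied by the criterion counts (two tests per
criterion: month and year). The rank-sum test enumerates the exact
midrank distribution when the pooled sample is small (≤ 12 by default)
and otherwise uses the tie-corrected normal approximation with
continuity correction; exhaustively over all tie-free outcomes at 8 per
group the two branches never differ by more than 0.011 in $p$.

## The synthetic respondents

No external data are required: seeded generators produce respondents
and their behavior so the whole pipeline is testable.

* **Latent structure.** A standardized patience trait $z$ drives both
  the discount factors (through a Gaussian copula with correlation 0.7,
  so tests and criteria share a weak common cause) and the criterion
  variables. `d_near` is Beta(7, 3) — median near 0.7, matching typical
  observed score medians — and `d_far` equals `d_near` for a stationary
  10% and is perturbed (SD 0.1) otherwise.
* **Choices.** A respondent prefers LL iff $d \cdot \mathrm{LL} >
  \mathrm{SS}$ and complies with that preference with probability 0.75 —
  deliberately equal to the bisection test's own $p_c$ assumption. Exact
  indifference is resolved by a fair coin (unbiased and testable).
* **Catch trials and slips.** Constant-consistency responding is a poor
  model for *obvious* items: at compliance 0.75, three or more failures
  among eight catch trials would occur for roughly a third of
  respondents, an order of magnitude above what attentive humans
  produce. Catch items are therefore answered correctly with
  probability 0.97 by attentive respondents, and a 5% careless fraction
  (compliance 0.55, plus a 15% per-trial chance of a matching slip
  below SS) supplies the realistic handful of excluded subjects.
  Attentive respondents never state an LL below SS. Matching answers
  are `SS/d` times lognormal noise with median 1 (log-SD 0.1), rounded
  to cents.
* **Criteria.** Binary behaviors are probit-coupled to $z$ with a
  loading calibrated by quadrature so that the asymptotic Efron's $R^2$
  of a probit on $z$ equals the configured `effect_size` (default 0.03,
  the weak-association regime); continuous behaviors get linear
  couplings with $R^2$ = `effect_size` on the coded scale. With
  `effect_size = 0` every criterion is independent of every latent.
* **Patience pairs.** Zero-inflated (default 5%) lognormal integers
  whose log-location decreases in $z$, with a shared within-respondent
  component linking month and year answers, heaped onto round numbers
  (one significant digit with probability 0.7, otherwise two) to
  reproduce the coexistence of very common response pairs and
  singletons that the nominal model feeds on.

The generators emulate structure, not people: no claim is made that
they reproduce any published table numerically. In particular the
constant-consistency choice model makes the simulated fixed test less
reliable than real fixed-test data (real consistency rises with
distance from indifference), simulated respondents have no memory
across rounds (real immediate retests are inflated by response
recall), and attrition between sessions is random rather than
selective. Passing tests therefore demonstrate that the *machinery* —
administration, scoring, coding, exclusion, evaluation — behaves as
specified, not that the behavioral model is right.

## Problem sizes and numerical conventions

The test suite exercises the headline patterns at the scales the
analyses are designed for: the association-without-prediction pattern
on 100 replicate cohorts of 181 respondents with 10 criteria
(`effect_size = 0`), and the nominal-versus-log overfitting pattern on
20 cohorts of 7,000 respondents with all 40 criteria. Bisection
recovery is checked noiselessly for $d = 0.1, \dots, 0.9$ (within 0.05
after 20 trials on the 1024-point grid) and as test–retest stability at
consistency 0.75 across 500 simulated respondents (median absolute
difference below 0.1). Posterior normalization is verified to $10^{-12}$
across $10^4$ random update sequences.

Other conventions worth knowing: quantiles everywhere use R's type-7
linear interpolation; PVAF uses the population variance of the target;
binary point predictions use $p \ge 0.5$; ordinal point predictions use
the argmax category; k-fold partitions are unstratified and balanced
(sizes differ by at most one); median regression uses the
Barrodale–Roberts simplex for $n \le 2000$ and the Frisch–Newton
interior-point method above; degenerate folds and models fall back to
intercept-only predictions and are counted, never silently dropped.

## Limitations

The package evaluates *tests*, not discounting *models*: no hyperbolic
or exponential discount-rate parameter is estimated anywhere, by
design. The respondent model is a stand-in with known idealizations
(see above). The nominal-dominance property (nominal in-sample
association at least matching the log model's) is an empirical
regularity of flexible class-based fitting, not a theorem — with very
small samples and extreme base rates the pooled singleton class can
lose to the probit by a fraction of a percentage point — and the
property suite checks it at realistic sizes. Ordinal probit fits with
very few cases per category may fall back to intercept-only
predictions, which slightly flatters the baseline in tiny samples.
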