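---
title: "Pattern discovery for imbalanced categorical targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern discovery for imbalanced categorical targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patdisc)
```

## The problem

Routine clinical repository data is categorical (or categorisable), noisy,
incomplete, and imbalanced: the outcomes worth predicting — death within a
follow-up window, bleeding after an intervention — occur in well under half
of records, often under 15%. Two consequences drive the design here.
First, accuracy is a useless criterion: predicting every record negative
scores `1 - prevalence`. Second, the consumers of the model are clinicians
who need a rule they can read, criticise and apply to a chart by hand, not
a coefficient vector.

## The pattern model

A pattern is `{P, S, r}`: attributes `P = (P_1, ..., P_w)`, one category
per attribute `S = (v_1, ..., v_w)`, and a matching-ratio threshold
`r` in (0, 1]. A record matches when

```
#{k : record[P_k] == v_k} / w >= r
```

with the convention that a missing cell equals nothing — not even another
missing cell. The threshold is the noise-tolerance dial: at `r = 1` the
pattern is an exact conjunction; at `r = 2/3` on a width-3 pattern, any two
of the three attribute-values suffice, so a record with one missing or
aberrant cell can still match. The denominator is the pattern width `w`,
never the total attribute count of the dataset: a threshold should not
change meaning because an irrelevant column was added. Comparison is
`>=`, so a record matching exactly `r·w` values matches. Internally the
test is done by the same floating division on both sides, which is exactly
equivalent to the integer rule `matched >= k` for every grid threshold
`k/w` up to width 64 (verified exhaustively in the tests).

Prediction quality for a minority positive class is summarised by the
F1-score (harmonic mean of precision and sensitivity, defined 0 when
TP = 0) and by the G-mean, the geometric mean of sensitivity and
specificity. The G-mean is the training criterion: it is zero as soon as
either rate collapses, so it punishes the all-negative degenerate solution
that imbalance invites. All metrics are total functions here — every
zero-denominator case returns 0 — so cross-validation aggregation never
drops folds.

## Training

Exhaustive search over attribute-value-threshold combinations is
intractable, so training is a three-stage heuristic, each stage cheap and
auditable:

1. **Attribute selection.** Each attribute is tested for independence
   against the binarised target (positive vs pooled negatives) with a
   Pearson chi-squared test on its contingency table over non-missing
   cells, without continuity correction. Attributes are ranked by ascending
   p-value (ties: descending statistic, then column order) and kept either
   up to a fixed width `W` or by the cutoff `p <= 0.05` (the default).
   An attribute with a single observed category is assigned statistic 0 and
   p-value 1 — uninformative, ranked last, but not an error; an all-missing
   attribute is dropped with a warning. No minimum expected-count rule is
   enforced (clinical tables are small); the ranking records whether all
   expected counts reached 5.
2. **Value selection.** For each kept attribute the two-row
   class-conditional percentage table is built (rows: positive, negative;
   columns: categories; missing cells excluded) and compared column-wise.
   The default `dominant-positive` heuristic returns the category with the
   largest positive-row percentage among those where the positive
   percentage is at least the negative one, falling back to the overall
   positive-row argmax when no column qualifies. The phrasing of this
   heuristic admits a second reading, so an alternative `max-difference`
   mode (argmax of positive-minus-negative percentage) is exposed in
   `pd_config()`; one is the default, both are documented, and ties always
   break to the earliest category in domain order.
3. **Threshold search.** With `P` and `S` fixed, `r` sweeps the complete
   grid `1/w, ..., w/w`, each point evaluated on the training data, and the
   best training G-mean wins. As `r` grows the match set shrinks
   monotonically, so sensitivity is non-increasing and specificity
   non-decreasing along the grid. Ties break to the largest `r` by default
   — the strictest pattern, favouring specificity on unseen data — with
   `smallest` available.

G-mean optimisation happens on training data only; test folds are never
consulted.

### The log-likelihood fallback

A single pattern can be too weak to catch every true positive when the
target is rare. When the training positive/negative ratio is below the
trigger (default 2, the smallest integer above the balanced-data boundary
of 1), the package also fits a Naive-Bayes-style table over the selected
attributes: class-conditional category probabilities with additive
smoothing (default pseudo-count 1) over each attribute's category domain,
missing cells excluded, plus class priors from training frequencies. With
2 positives of which 2 have `PCI = Yes` and a two-category domain, add-1
smoothing gives `P(Yes | positive) = (2+1)/(2+2) = 0.75`. A category never
seen in a class keeps strictly positive mass, so log scores are always
finite; a category outside the training domain altogether scores the
smoothing-only mass `s/(n_class + s·d)`. Prediction is then

```
positive  <=>  match(pattern, record)  OR  loglik(+|record) > loglik(-|record)
```

with strict inequality — ties are negative — and the likelihood sum
skipping missing cells. Whether class priors belong in the comparison is
genuinely open; since the fallback is Naive-Bayes scoring, priors are
included by default, and `pd_config(include_priors = FALSE)` gives the
pure-likelihood variant. With no fallback fitted, prediction is exactly
the pattern match.

## Evaluation framework

`run_experiment()` implements the repeated stratified cross-validation
protocol: each run draws seeded stratified folds (per-fold class counts
within one of each other) shared by *all* compared methods; each training
portion may be up-sampled to a requested positive/negative ratio by
duplicating existing positive records uniformly at random — never
synthesising values, never touching negatives, and never touching the test
fold; the run-level value of each metric is the mean over the k test folds,
and the report aggregates mean ± sd over the run-level values. Method
comparisons use the one-sided paired Wilcoxon signed-rank test
(alternative: pattern discovery greater), normal approximation with zero
differences dropped, average ranks with the tie-corrected variance, and —
deliberately — no continuity correction: with 20 pairs all favouring one
method by distinct margins this gives p = 4.43e-5, whereas the corrected
and exact variants give ≈ 4.8e-5 and ≈ 9.5e-7. The uncorrected
approximation is the default; both alternatives are flags.

The fair-coin baseline predicts positive with probability 1/2 regardless
of input, giving theoretical sensitivity and specificity 0.5 and precision
equal to prevalence, hence theoretical F1 `2·p·0.5/(p + 0.5)` — 0.23 at
14.9% prevalence. Logistic regression, naive Bayes and a CART decision
tree are available as plug-in comparators behind the same protocol, run at
their host-package defaults; their exact numerics are ecosystem-dependent
and are not treated as a contract.

Folds are assembled first and the training portion up-sampled afterwards;
re-stratifying after up-sampling would leak duplicated positives across
the train/test boundary.

## The synthetic generator

`synthetic_dataset()` emulates the data regime the method targets:
minority prevalence (the positive count is exact, `round(n·prevalence)`,
so the imbalance trigger and fold stratification are deterministic test
surfaces), a planted width-`w` attribute-value pattern carried by each
positive with probability `adherence_pos` and each negative with
`adherence_neg` (non-adherent cells fall back uniformly to the other
categories — the simplest null), uniform target-independent noise
attributes, and per-cell missingness (never on the target). The defaults —
500 records, 10% prevalence, width 4, adherence 0.9/0.2, ten noise
attributes of three categories, 1% missing — are the recovery conditions
used throughout the tests, chosen to sit inside the prevalence (9–15%) and
missingness (0.3–3%) range of realistic repository extracts.

What the generator does *not* emulate: correlated predictors, structured
(non-random) missingness, multi-way interactions, or the covariance of
derived gene-expression components. Passing tests therefore demonstrate
that the algorithm recovers a planted signal under independent categorical
noise — not that it will rank attributes correctly under collinearity,
where chi-squared selection can pick redundant proxies.

## Numerical choices and degenerate inputs

* Missing cells are excluded from chi-squared tables, percentage tables
  and likelihood sums, and count as mismatches during matching; no
  imputation anywhere.
* Intervals in categorisation rules are half-open `[low, high)`; the sign
  rule sends 0 to the non-positive label. A non-missing value outside all
  bins is an error, forcing rule completeness.
* Numeric columns are refused by the trainer until explicitly categorised
  — the categorisation step is part of the audit trail.
* Serialization snaps a reloaded threshold to the nearest `k/w` within
  1e-9, since YAML float rounding could otherwise flip an exact-boundary
  match.
* Empty datasets, single-class targets, missing target cells, and
  patterns referencing absent attributes are errors, not silent results.

## Problem sizes in the test suite

The suite runs the worked six-record example exactly; threshold-grid
optimality is checked against a brute-force enumeration oracle on 100
generated datasets (n ≤ 60, width ≤ 4); planted-pattern recovery uses 20
generator seeds at n = 500 and a 20-run 10-fold cross-validation against
the baseline on one n = 500 dataset; the baseline calibration uses draws
of 10^5. These sizes give stable statistical assertions (3-standard-error
bands) while keeping the default run in tens of seconds.

## Limitations

Single pattern, single value per attribute: records expressing the target
through two disjoint mechanisms are only partially covered (the likelihood
fallback softens, but does not remove, this). Attribute selection is
marginal, so correlated predictors can crowd out a conditionally
informative one. The trigger ratio 2 and the p-cutoff 0.05 are pragmatic
defaults, not tuned quantities. Automatic binning of numeric attributes is
out of scope by design — thresholds carry clinical meaning and should come
from the user.
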