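---
title: "Permutation importance of TFI frailty items: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation importance of TFI frailty items: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfiperm)
```

## The scientific question

The Tilburg Frailty Indicator (TFI) asks fifteen yes/no questions (items
TFI11--TFI25) spanning a physical domain (TFI11--TFI18), a psychological
domain (TFI19--TFI22) and a social domain (TFI23--TFI25). In clinical
cohorts --- the motivating case is heart-failure patients screened for
frailty syndrome --- one wants to know which items carry diagnostic
information about the frailty label, both in absolute terms ("does the
model rely on this item?") and relative terms ("is low mood more
informative than weak hand grip?"). `tfiperm` implements that analysis:
tree-based classifiers on the binary items, permutation feature importance
with a z significance test, and Bonferroni-corrected pairwise comparisons
of item importances.

Because the motivating study's patient-level data are not public, the
package ships a synthetic-cohort generator that reproduces the *structure*
of such data, so every stage of the pipeline is testable end to end.

## The synthetic cohort generator

`generate_cohort(cohort_spec(...))` draws, per participant:

* a frailty label, Bernoulli with prevalence 562/666 ≈ 0.844 by default
  (the class balance of the motivating sample of 666 patients);
* each of the 15 items independently, Bernoulli with a class-conditional
  probability from an `item_profile`. Two default pairs are reference
  values from the motivating study --- TFI17 (hand strength) 0.61 frail vs
  0.07 non-frail, and TFI23 (living alone) 0.31 vs 0.16; the other 13
  pairs are implementation defaults chosen to be clinically plausible and
  are fully overridable. Three items (TFI11, TFI22, TFI25) are
  reverse-coded ("yes" = good function) and deliberately left unrecoded,
  which is why descriptive summaries use absolute differences;
* class-conditional demographics (age, sex, relationship, education,
  income band, diabetes, hypertension) approximating the study's
  sample-characteristics table. The classifiers never see them; they exist
  to exercise the reporting path.

Record-level missingness is missing-completely-at-random: each record is
independently selected with probability 54/666 by default and has one
uniformly chosen item blanked, so an n = 666 cohort keeps about 612
complete cases. The study only reports the complete-case count, not the
missingness pattern; MCAR is the simplest mechanism that exercises the
complete-case filter and is a stand-in, not an inference about the study.
All draws flow from one integer seed through independent derived
sub-streams, so a spec is a complete, reproducible description of a
cohort.

What the generator deliberately does **not** model: item--item correlation
beyond what the shared label induces, informative (MAR/MNAR) missingness,
and any longitudinal structure. Passing tests on synthetic cohorts
therefore demonstrate the correctness of the machinery and the behaviour
of the statistics under class-conditional independence --- not that real
TFI data satisfy those assumptions.

## Preprocessing

`drop_incomplete()` keeps records with all 15 items present (idempotent,
order-preserving). `split_dataset()` assigns complete cases at random to
train/validation/test with fractions 4/6, 1/6, 1/6: the train size is
`round(4n/6)` and the remainder is split as evenly as possible with any
odd record going to validation (so 612 → 408/102/102 and 6 → 4/1/1).
Indices are 1-based row positions, R's native convention. The split is
unstratified by default, matching a plain randomizing function; a
stratified-by-label option exists because at 15% non-frail prevalence a
small cohort can otherwise lose a class from a subset.

## The three classifiers

All models see only the 15 binary items; frail (1) is the positive class.

* **Decision tree** --- `rpart`, with `maxdepth` and a minimum leaf size
  expressed as a data fraction (`minbucket = ceiling(fraction * n)`),
  `cp = 0` so the two stated parameters are the only complexity controls.
  Reference configuration: depth 3, leaf fraction 0.1.
* **Random forest** --- `ranger`, which exposes the same two controls
  (`max.depth`, `min.bucket`). Reference configuration: depth 4, leaf
  fraction 0.03, 100 trees. A predict-time seed is pinned because ranger
  breaks exact vote ties randomly; predictions are then deterministic.
* **AdaBoost** --- discrete two-class AdaBoost (SAMME) implemented in the
  package over weighted `rpart` base learners, since no boosting package
  of that family is a dependency. Reference configuration: 200 depth-1
  stumps. Rounds stop early if a learner reaches weighted error ≥ 0.5 or
  fits perfectly; prediction is the sign of the alpha-weighted vote, with
  exact ties resolved to the positive class (documented, deterministic).

**Hyperparameter selection** (`select_hyperparameters()`) fits every grid
point (default: depth 1--6 × leaf fraction {0.01, 0.03, 0.05, 0.1, 0.2},
estimator counts held at 1/100/200) on train and scores it on validation.
The protocol treats the two error types on an equal footing: maximise
`min(TPR, TNR)`, break ties by higher `TPR + TNR`, then prefer the lowest
complexity under the lexicographic order (smaller depth, fewer estimators,
larger leaf fraction). The "balance then simplicity" objective is one
concrete operationalisation of treating true positives and true negatives
equally; nothing in the data forces this form, so it is exposed and
documented rather than hidden.

## Absolute importance: permutation drops and the z test

For a fitted model, evaluation data of size n and feature j,
`permutation_importance()` computes the baseline accuracy once, then for
each of R repeats permutes column j within the subset (labels and other
columns untouched) and records the drop

$$d_r = \mathrm{acc}_{\text{baseline}} - \mathrm{acc}_{\text{perm},r}.$$

The summary is the mean drop $\mu$, the population standard deviation
$\sigma$ (divide-by-R; at R = 10000 the distinction from divide-by-(R−1)
is negligible, but one convention must be fixed), and

$$z = \frac{\mu\sqrt{R}}{\sigma}, \qquad p = 1 - \Phi(z) \text{ (one-tailed)}.$$

This is a one-sample z on the mean drop, which is why z grows with the
number of permutations while $\sigma$ is reported unscaled. R defaults to
10000: across the twelve reference $(\mu, \sigma, z)$ triples of the
motivating study the relation $z = \mu\sqrt{R}/\sigma$ reproduces the
reported z values within 5% exactly when $\sqrt{R} \approx 100$
(`reference_importance_stats()` carries the triples;
`importance_z(0.082, 0.036, 1e4)` ≈ 227.8 against a reported 230.1).

A feature the model never consults yields all-zero drops; by convention
its z is undefined and p = 1 (no NaN propagation), and downstream code
flags it as `zero_importance`. Permutations are always within one subset
(validation or test), never across the split.

## Relative importance: pairwise z and Bonferroni correction

`pairwise_compare()` tests $\Delta = \mu_a - \mu_b$ with the unpaired
pooled form

$$z = \frac{\Delta\sqrt{R}}{\sqrt{\sigma_a^2 + \sigma_b^2}},
  \qquad p = 2\,(1 - \Phi(|z|)),$$

a positive $\Delta$ meaning feature a is diagnostically more important.
The unpaired form was chosen because it reproduces all three reference
decision-tree $(\Delta, z)$ pairs within rounding of the reported inputs
(e.g. `pairwise_z(0.082, 0.036, 0.062, 0.025, 1e4)` ≈ 45.6 against a
reported 46), whereas a paired statistic cannot be reconstructed without
per-repeat draws. A normal rather than t reference is used since
R = 10000 makes them indistinguishable.

Significance uses the Bonferroni per-comparison threshold
$\alpha/m$. The family size m is a modelling choice, so it is
configurable with two conventions: all pairs among the variables the
model actually used (m = 3 for a three-variable decision tree, threshold
0.0167) or all C(15,2) = 105 item pairs (threshold ≈ 0.0005). The
hypothesis-driven set --- 7 psychosocial items × 3 selected physical items
(TFI13 walking, TFI17 hand strength, TFI18 fatigue) = 21 comparisons ---
is treated as a reporting subset, not a correction family. When exactly
one feature of a pair has undefined (all-zero) importance, the other is
declared more important whenever its own one-tailed test clears the
threshold: a variable that never entered the model is dominated by every
variable that did and matters.

`comparison_matrix()` assembles the antisymmetric $\Delta$ and z matrices
with a symmetric significance mask and a never-significant diagonal.

## Numerical and implementation choices

* **Exact lookup-table prediction.** All features are binary, so any
  fitted model is equivalent to a table over the $2^{15}$ item patterns.
  Each model memoises that table with one bulk predict call, after which a
  permutation repeat costs O(n) integer indexing. This makes R = 10000
  permutation importance exact and cheap; it is an implementation of the
  same predictor, not an approximation.
* **Determinism.** Every stochastic operation takes a seed; identical
  inputs give byte-identical outputs, and `run_pipeline()` writes a
  manifest with file checksums so reproducibility is checkable.
* **Degenerate inputs.** Single-class data, empty grids, all-missing
  cohorts, constant feature columns, and absent evaluation classes all
  have defined behaviour (errors naming the problem, or NA-with-reason
  rates) rather than silent zeros.

## Known limitations

* **The one-tailed importance z test is not α-calibrated under the
  null.** All R drops share one baseline accuracy. For a genuinely
  label-independent feature the baseline is exchangeable with the
  permuted accuracies, so the mean drop has standard deviation of order
  $\sigma$, not $\sigma/\sqrt{R}$, and the z statistic is far
  overdispersed relative to N(0,1). In practice the test's null rejection
  rate is a mixture: essentially 0 when the model ignores the feature
  (all drops are exactly zero) and substantially above the nominal level
  when the model consults it. The package's simulation suite measures
  this directly; the z and p values should therefore be read as
  *descriptive rankings with a significance-style display*, as is common
  for permutation importances, not as calibrated hypothesis tests.
* Class-conditional independence in the generator understates the
  redundancy of real questionnaire items; relative-importance contrasts
  on real data will typically be attenuated by inter-item correlation.
* With ~16% non-frail prevalence, validation and test subsets of ~100
  records contain few negatives, so TNR estimates are coarse (steps of
  1/16 at the study's scale) and validation-selected models can shift
  noticeably on test --- the overfitting pattern the selection protocol
  cannot fully remove.

## Problem sizes used by the test suite

The packaged tests run cohorts of 150--900 records with R = 20--200
permutation repeats for structural and property checks; the deeper
simulation checks use n = 5000 with R = 1000 (signal recovery across all
three model families) and 200 replicates of n = 666 with R = 200 (null
rejection rate). These sizes were chosen so each statistical property is
tested at meaningful power while the whole suite stays comfortably
rerunnable on a laptop.
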